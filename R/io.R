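# ---- session tables and configuration ----------------------------------

#' Write / read a long-format session table as TSV
#'
#' The on-disk format is UTF-8 tab-separated text with a header row and
#' columns `participant`, `run`, `trial`, `item`, `response`, `feedback`;
#' missing responses are encoded as the literal token `NA`. The round trip
#' is lossless. On reading, rows are validated against the design: values
#' outside the rating scale, duplicate (participant, run, trial) keys, and
#' missing feedback are rejected with the offending line numbers.
#'
#' @param session a session table (see [apply_exclusions()]).
#' @param path file path.
#' @param design a [build_design()] object used for validation.
#' @return `read_session` returns the validated data.frame.
#' @export
write_session <- function(session, path) {
  check_session(session)
  write.table(session[, c("participant", "run", "trial", "item", "response",
                          "feedback")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, design) {
  df <- read.delim(path, na.strings = "NA", stringsAsFactors = FALSE)
  check_session(df)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stop(what, " at line(s) ",
           paste(head(line[which(cond)], 10), collapse = ", "))
  }
  bad(is.na(df$feedback), "missing feedback")
  in_scale <- function(x) x >= design$scale_min & x <= design$scale_max
  bad(!is.na(df$response) & !in_scale(df$response),
      "response outside the rating scale")
  bad(!in_scale(df$feedback), "feedback outside the rating scale")
  bad(!(df$item %in% design$items), "unknown item")
  key <- paste(df$participant, df$run, df$trial)
  bad(duplicated(key), "duplicate (participant, run, trial) key")
  df
}

#' Split a session table into per-participant run lists
#'
#' Converts the long format into the `runs` format that [fit_model()]
#' expects: a named list (one element per participant) of lists of per-run
#' data.frames ordered by trial.
#'
#' @inheritParams write_session
#' @return named list of run lists.
#' @export
session_to_runs <- function(session) {
  check_session(session)
  lapply(split(session, session$participant), function(p) {
    lapply(split(p, p$run), function(r) {
      r <- r[order(r$trial), c("trial", "item", "response", "feedback")]
      rownames(r) <- NULL
      r
    })
  })
}

# configuration schema: every key with its default; NULL means no default
config_schema <- function() {
  list(
    preset = "exp1",
    seed = 1L,
    models = c("M1", "M2", "M3", "M4", "M5"),
    population = list(within_factor_loading = 0.6, n_raters = 300,
                      rating_sd = 1.5),
    fitting = list(reltol = 1e-6, maxit = 2000, n_starts = 1),
    recovery = list(n_reps = 200, param_low = 0, param_high = 1,
                    noise_sd = 1),
    confusion = list(n_reps = 200, param_low = 0.2, param_high = 0.8,
                     noise_sd = 1),
    bms = list(alpha0 = 1, n_mc_samples = 1e6)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON-style YAML) configuration declaring the design
#' preset, the model set, seeds, and fitting / comparison / validation
#' options. Unknown keys are rejected; omitted keys are filled with the
#' documented defaults (see [config_schema] via `load_config(NULL)`).
#'
#' @param path path to a YAML file, or `NULL` for the pure defaults.
#' @return fully-defaulted configuration list of class `tl_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (grp in c("population", "fitting", "recovery", "confusion", "bms")) {
    if (!is.null(cfg[[grp]])) {
      bad <- setdiff(names(cfg[[grp]]), names(schema[[grp]]))
      if (length(bad))
        stop("unknown key(s) in '", grp, "': ", paste(bad, collapse = ", "))
    }
  }
  out <- utils::modifyList(schema, cfg)
  if (!out$preset %in% c("exp1", "exp2", "exp3", "exp4", "exp5"))
    stop("unknown preset '", out$preset, "'")
  for (grp in c("recovery", "confusion")) {
    g <- out[[grp]]
    if (g$param_low >= g$param_high)
      stop("in '", grp, "': param_low must be below param_high")
    if (g$param_low < 0 || g$param_high > 1)
      stop("in '", grp, "': parameter draw bounds must lie within [0, 1]")
  }
  if (out$population$within_factor_loading <= 0 ||
      out$population$within_factor_loading >= 1)
    stop("within_factor_loading must lie in (0, 1)")
  if (!all(out$models %in% c("M1", "M2", "M3", "M4", "M5")))
    stop("models must be a subset of M1..M5")
  structure(out, class = "tl_config")
}

#' @rdname load_config
#' @param config a `tl_config` to serialize.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
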