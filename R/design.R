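#' Build an experiment design
#'
#' Constructs the layout of a trait-learning experiment: the item set, the
#' mapping of items to personality factors, the rating-scale bounds, the
#' number of profiles (runs) and the number of trials per run (one trial per
#' item, presented in a random order each run).
#'
#' Five presets cover the canonical task layouts:
#' \describe{
#'   \item{exp1}{60 trait adjectives, 5 Big-Five factors with unequal item
#'     counts (19, 13, 10, 10, 8), scale 1-8, 4 profiles, mixed valence.}
#'   \item{exp2}{60 positive traits, 2 factors (agreeableness,
#'     conscientiousness) of 30 items, scale 1-8, 4 constructed profiles.}
#'   \item{exp3}{as exp2 but profiles sampled from real raters.}
#'   \item{exp4}{as exp1; the out-group variant with a stereotype reference
#'     point.}
#'   \item{exp5}{50 IPIP-style statements, 5 factors of 10 items, scale 1-5,
#'     5 profiles, mixed valence.}
#' }
#'
#' @param preset one of `"exp1"` ... `"exp5"`, or `NULL` when `config` is
#'   given.
#' @param config optional list with elements `items` (character ids),
#'   `factor_of` (character vector, one factor label per item), `scale_min`,
#'   `scale_max`, `n_profiles`, and optionally `valence` (+1/-1 per item,
#'   default all +1).
#' @return an object of class `tl_design`: a list with elements `items`,
#'   `factor_of` (named by item), `factors`, `valence` (named, +1/-1),
#'   `scale_min`, `scale_max`, `n_profiles`, `n_trials_per_run`, `preset`.
#' @examples
#' d <- build_design("exp1")
#' d$n_trials_per_run  # 60
#' table(d$factor_of)
#' @export
build_design <- function(preset = NULL, config = NULL) {
  if (!is.null(preset)) {
    presets <- c("exp1", "exp2", "exp3", "exp4", "exp5")
    if (!preset %in% presets)
      stop("unknown preset '", preset, "'; must be one of ",
           paste(presets, collapse = ", "))
    config <- switch(preset,
      exp1 = , exp4 = list(
        factor_sizes = c(N = 19, E = 13, O = 10, A = 10, C = 8),
        scale_min = 1, scale_max = 8, n_profiles = 4, mixed_valence = TRUE),
      exp2 = , exp3 = list(
        factor_sizes = c(A = 30, C = 30),
        scale_min = 1, scale_max = 8, n_profiles = 4, mixed_valence = FALSE),
      exp5 = list(
        factor_sizes = c(N = 10, E = 10, O = 10, A = 10, C = 10),
        scale_min = 1, scale_max = 5, n_profiles = 5, mixed_valence = TRUE))
    sizes <- config$factor_sizes
    factor_of <- rep(names(sizes), times = sizes)
    n <- length(factor_of)
    items <- sprintf("item%02d", seq_len(n))
    # deterministic alternation of valence within each factor so the
    # structure does not depend on any random seed
    valence <- if (isTRUE(config$mixed_valence)) {
      unlist(lapply(sizes, function(k) rep_len(c(1, -1), k)), use.names = FALSE)
    } else rep(1, n)
    config <- list(items = items, factor_of = factor_of,
                   scale_min = config$scale_min, scale_max = config$scale_max,
                   n_profiles = config$n_profiles, valence = valence)
  }
  if (is.null(config)) stop("either 'preset' or 'config' must be supplied")
  items <- as.character(config$items)
  factor_of <- as.character(config$factor_of)
  if (length(factor_of) != length(items))
    stop("factor_of must give exactly one factor label per item")
  if (anyDuplicated(items)) stop("item ids must be unique")
  smin <- as.numeric(config$scale_min)
  smax <- as.numeric(config$scale_max)
  if (!(smin < smax)) stop("scale_min must be less than scale_max")
  valence <- config$valence
  if (is.null(valence)) valence <- rep(1, length(items))
  if (!all(valence %in% c(-1, 1)))
    stop("valence must be +1 or -1 per item")
  if (!is.null(config$n_trials_per_run) &&
      config$n_trials_per_run != length(items))
    stop("n_trials_per_run must equal the number of items (", length(items),
         "): each item is presented exactly once per run")
  design <- structure(list(
    items = items,
    factor_of = setNames(factor_of, items),
    factors = unique(factor_of),
    valence = setNames(as.numeric(valence), items),
    scale_min = smin, scale_max = smax,
    n_profiles = as.integer(config$n_profiles %||% 1L),
    n_trials_per_run = length(items),
    preset = preset %||% "custom"
  ), class = "tl_design")
  design
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tl_design <- function(x, ...) {
  cat("Trait-learning experiment design (", x$preset, ")\n", sep = "")
  cat("  items:", length(x$items), "in", length(x$factors), "factors (",
      paste(sprintf("%s:%d", x$factors, table(x$factor_of)[x$factors]),
            collapse = ", "), ")\n")
  cat("  scale: [", x$scale_min, ",", x$scale_max, "]  profiles:",
      x$n_profiles, "  trials/run:", x$n_trials_per_run, "\n")
  invisible(x)
}

# integer item indices for a character item vector
item_index <- function(items, design) {
  idx <- match(items, design$items)
  if (anyNA(idx)) stop("unknown item(s): ",
                       paste(items[is.na(idx)], collapse = ", "))
  idx
}

# round half away from zero (all ratings are positive, so floor(x + 0.5)),
# then cap to the rating scale; preserves matrix shape
round_cap <- function(x, design) {
  cap_scale(floor(x + 0.5), design)
}

cap_scale <- function(x, design) {
  x[x < design$scale_min] <- design$scale_min
  x[x > design$scale_max] <- design$scale_max
  x
}
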