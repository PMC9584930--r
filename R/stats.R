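# ---- model-free behavioural statistics ---------------------------------

# a session table is a long data.frame with columns participant, run,
# trial, item, response (NA = missing), feedback
check_session <- function(session) {
  need <- c("participant", "run", "trial", "item", "response", "feedback")
  miss <- setdiff(need, names(session))
  if (length(miss))
    stop("session table is missing column(s): ", paste(miss, collapse = ", "))
  session
}

#' Apply missing-data exclusion rules
#'
#' Participants who miss more than 10% of all their answers are removed
#' entirely; of the remaining participants, any single run with more than
#' 20% missing answers is removed (both thresholds strict). Every removal is
#' logged with its missing fraction.
#'
#' @param session a long session table (columns `participant`, `run`,
#'   `trial`, `item`, `response` with NA marking a missing answer,
#'   `feedback`).
#' @return list with `data` (the filtered table) and `log` (data.frame of
#'   removals: level, participant, run, missing fraction).
#' @examples
#' s <- data.frame(participant = 1, run = rep(1:2, each = 10), trial = 1:10,
#'                 item = paste0("item", 1:10),
#'                 response = c(rep(NA, 3), rep(5, 7), rep(5, 10)),
#'                 feedback = 5)
#' apply_exclusions(s)$log  # run 1 has 30% missing
#' @export
apply_exclusions <- function(session) {
  check_session(session)
  missing <- is.na(session$response)
  log <- data.frame(level = character(0), participant = character(0),
                    run = character(0), fraction = numeric(0),
                    stringsAsFactors = FALSE)
  p_frac <- tapply(missing, session$participant, mean)
  drop_p <- names(p_frac)[p_frac > 0.10]
  for (p in drop_p)
    log <- rbind(log, data.frame(level = "participant", participant = p,
                                 run = NA_character_,
                                 fraction = unname(p_frac[p])))
  keep <- !(as.character(session$participant) %in% drop_p)
  session <- session[keep, , drop = FALSE]
  if (nrow(session)) {
    key <- interaction(session$participant, session$run, drop = TRUE)
    r_frac <- tapply(is.na(session$response), key, mean)
    drop_r <- names(r_frac)[r_frac > 0.20]
    for (k in drop_r) {
      row1 <- session[key == k, ][1, ]
      log <- rbind(log, data.frame(level = "run",
                                   participant = as.character(row1$participant),
                                   run = as.character(row1$run),
                                   fraction = unname(r_frac[k])))
    }
    session <- session[!(key %in% drop_r), , drop = FALSE]
  }
  list(data = session, log = log)
}

#' Absolute prediction-error trend over trials
#'
#' Computes the participant PE (feedback minus response) per trial, averages
#' the absolute PEs over runs (profiles) within participant and then over
#' participants to one value per trial position, and correlates that vector
#' with the trial number. A negative Pearson r indicates learning (shrinking
#' errors).
#'
#' @inheritParams apply_exclusions
#' @return object of class `tl_pe_trend`: list with `mean_abs_pe` (per trial
#'   position), `r` (Pearson correlation vs trial number; NA with
#'   `degenerate = TRUE` when the PE profile is constant), `n_trials`.
#' @export
pe_trend <- function(session) {
  check_session(session)
  nt <- max(session$trial)
  if (nt < 3) stop("at least 3 trial positions are required")
  abs_pe <- abs(session$feedback - session$response)
  # profiles -> participant x trial means -> grand mean per trial
  per_pt <- tapply(abs_pe, list(session$participant, session$trial),
                   mean, na.rm = TRUE)
  mean_abs_pe <- colMeans(per_pt, na.rm = TRUE)
  trials <- as.numeric(colnames(per_pt))
  degenerate <- sd(mean_abs_pe, na.rm = TRUE) == 0
  r <- if (degenerate) NA_real_ else cor(trials, mean_abs_pe,
                                         use = "complete.obs")
  structure(list(mean_abs_pe = mean_abs_pe, trials = trials,
                 r = if (degenerate) 0 else r, degenerate = degenerate,
                 n_trials = nt),
            class = "tl_pe_trend")
}

#' @export
print.tl_pe_trend <- function(x, ...) {
  cat(sprintf("Mean |PE| over %d trial positions; Pearson r vs trial = %.3f%s\n",
              x$n_trials, x$r,
              if (x$degenerate) " (constant |PE|, degenerate)" else ""))
  invisible(x)
}

#' Build trial-level GLM regressors for one run
#'
#' For each trial of a run: regressor 1 counts the previous trials in the
#' run (standard Rescorla-Wagner learning), regressor 2 counts the previous
#' trials from the current item's factor (coarse granularity), and regressor
#' 3 sums the absolute correlations of all previously shown items with the
#' current item (fine granularity). The dependent variable is the trial's
#' absolute prediction error. All regressors are 0 on the first trial of a
#' run.
#'
#' @param run one run's trials in order: data.frame with columns `item`,
#'   `response`, `feedback` (and optionally `trial`).
#' @param design a [build_design()] object.
#' @param sim signed item x item similarity matrix; absolute values are used
#'   for regressor 3.
#' @return data.frame with columns `trial`, `reg1`, `reg2`, `reg3`, `dv`
#'   (NA where the response is missing).
#' @export
build_glm_regressors <- function(run, design, sim) {
  if ("trial" %in% names(run)) run <- run[order(run$trial), ]
  items <- as.character(run$item)
  if (anyDuplicated(items)) stop("items must be unique within a run")
  if (!all(items %in% rownames(sim)))
    stop("item(s) missing from the similarity matrix")
  nt <- length(items)
  fac <- design$factor_of[items]
  reg1 <- seq_len(nt) - 1
  reg2 <- vapply(seq_len(nt), function(t)
    if (t == 1) 0 else sum(fac[seq_len(t - 1)] == fac[t]), numeric(1))
  reg3 <- vapply(seq_len(nt), function(t)
    if (t == 1) 0 else sum(abs(sim[items[seq_len(t - 1)], items[t]])),
    numeric(1))
  dv <- abs(as.numeric(run$feedback) - as.numeric(run$response))
  data.frame(trial = seq_len(nt), reg1 = reg1, reg2 = reg2, reg3 = reg3,
             dv = dv)
}

#' Fit the trial-level GLM for one participant
#'
#' Ordinary least squares of the absolute prediction error on the three
#' regressors of [build_glm_regressors()] (rows from all runs concatenated;
#' regressors reset at each run start). Regressors are z-scored within
#' participant before fitting (betas become comparable across participants;
#' t statistics are invariant to this rescaling). Trials with missing
#' responses are dropped. Both modes of the analysis are available: each
#' regressor alone in its own regression (`type = "single"`, the default) or
#' all three jointly (`type = "joint"`).
#'
#' @param rows data.frame of regressor rows (concatenated runs) with columns
#'   `reg1`, `reg2`, `reg3`, `dv`.
#' @param type `"single"` or `"joint"`.
#' @return named numeric vector of slope estimates (`reg1`, `reg2`, `reg3`).
#'   For the joint fit, attributes `condition_number` and
#'   `rank_deficient` flag collinearity.
#' @export
fit_participant_glm <- function(rows, type = c("single", "joint")) {
  type <- match.arg(type)
  rows <- rows[!is.na(rows$dv), , drop = FALSE]
  if (nrow(rows) < 5) stop("at least 5 usable trials are required")
  zscore <- function(x) if (sd(x) == 0) x * 0 else (x - mean(x)) / sd(x)
  z <- data.frame(dv = rows$dv, reg1 = zscore(rows$reg1),
                  reg2 = zscore(rows$reg2), reg3 = zscore(rows$reg3))
  regs <- c("reg1", "reg2", "reg3")
  if (type == "single") {
    betas <- vapply(regs, function(rg)
      unname(coef(lm(stats::reformulate(rg, "dv"), data = z))[rg]),
      numeric(1))
    return(setNames(betas, regs))
  }
  fit <- lm(dv ~ reg1 + reg2 + reg3, data = z)
  betas <- coef(fit)[regs]
  betas[is.na(betas)] <- 0
  x <- as.matrix(z[, regs])
  sv <- svd(x)$d
  kappa <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  structure(setNames(unname(betas), regs),
            condition_number = kappa,
            rank_deficient = qr(x)$rank < length(regs))
}

#' Group-level one-sample t-test on GLM betas
#'
#' Tests whether the mean slope across participants differs from zero in the
#' stated direction (one-sided, no multiple-comparison correction). The
#' default direction is negative: learning predicts shrinking absolute
#' prediction errors.
#'
#' @param betas numeric vector, one slope per participant (>= 2).
#' @param direction `"less"` (negative slopes, the default) or `"greater"`.
#' @return list with `mean`, `t`, `p` (one-sided), `df`
#'   (`n_participants - 1`); `t` and `p` are NA (flagged via `degenerate`)
#'   when the betas have zero variance.
#' @export
group_ttest <- function(betas, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(betas) < 2) stop("at least 2 participants are required")
  if (sd(betas) == 0)
    return(list(mean = mean(betas), t = NA_real_, p = NA_real_,
                df = length(betas) - 1L, degenerate = TRUE))
  tt <- t.test(betas, mu = 0, alternative = direction)
  list(mean = mean(betas), t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter), degenerate = FALSE)
}
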