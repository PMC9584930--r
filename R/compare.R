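#' Fixed-effects model comparison (log-group Bayes factor)
#'
#' Sums BIC scores across participants per model and expresses each model as
#' the difference from the worst (highest-sum) model, so that larger deltas
#' indicate better models and the worst model scores 0.
#'
#' @param bic_table numeric subject x model matrix (or data.frame) of BIC
#'   scores with model names as column names; no missing cells.
#' @return list with `bic_sums` and `delta_vs_worst` (both named per model).
#' @examples
#' tab <- rbind(c(M2 = 120, M5 = 100), c(M2 = 130, M5 = 125))
#' fixed_effects_compare(tab)
#' @export
fixed_effects_compare <- function(bic_table) {
  bic_table <- as.matrix(bic_table)
  if (length(bic_table) == 0) stop("empty BIC table")
  if (anyNA(bic_table)) stop("BIC table contains missing cells")
  sums <- colSums(bic_table)
  list(bic_sums = sums, delta_vs_worst = max(sums) - sums)
}

#' Convert BIC to an approximate log model evidence
#'
#' BIC approximates -2 times the log model evidence, so the log evidence
#' used by the random-effects comparison is `-bic / 2`.
#'
#' @param bic numeric (vectorized).
#' @return `-bic / 2`.
#' @export
bic_to_log_evidence <- function(bic) {
  stopifnot(all(is.finite(bic)))
  -bic / 2
}

#' Random-effects Bayesian model selection (exceedance probabilities)
#'
#' Variational Bayesian model selection over a group: model frequencies in
#' the population get a Dirichlet prior with concentration `alpha0`, and the
#' posterior is found by iterating
#' \deqn{u_{nk} \propto \exp(\log ev_{nk} + \psi(\alpha_k) -
#'   \psi(\textstyle\sum_j \alpha_j)), \qquad
#'   \alpha_k = \alpha_{0} + \sum_n u_{nk}}
#' with per-subject normalization of u, until the concentration parameters
#' stabilize. Exceedance probabilities -- the posterior probability that
#' each model is the most frequent one in the population -- are estimated by
#' Monte-Carlo sampling from the posterior Dirichlet and counting argmax
#' frequencies.
#'
#' @param log_evidence subject x model matrix of log model evidences (see
#'   [bic_to_log_evidence()]).
#' @param alpha0 prior Dirichlet concentration (> 0, default 1: uniform).
#' @param n_mc_samples Monte-Carlo samples for the exceedance probabilities.
#' @param seed optional integer seed for the Monte-Carlo step.
#' @param max_iter,tol convergence control: stop when the largest change in
#'   any concentration parameter drops below `tol`, or after `max_iter`
#'   iterations (reported via `converged`).
#' @return object of class `tl_bms`: list with `dirichlet_alpha`,
#'   `expected_freq` (posterior mean frequencies, sums to 1),
#'   `exceedance_prob` (sums to 1 within Monte-Carlo error), `converged`,
#'   `n_iter`.
#' @examples
#' lev <- cbind(M2 = c(-50, -52, -49), M5 = c(-45, -50, -44))
#' bms_random_effects(lev, n_mc_samples = 1e4, seed = 1)
#' @export
bms_random_effects <- function(log_evidence, alpha0 = 1, n_mc_samples = 1e6,
                               seed = NULL, max_iter = 200, tol = 1e-6) {
  log_evidence <- as.matrix(log_evidence)
  if (anyNA(log_evidence) || any(!is.finite(log_evidence)))
    stop("log evidences must be finite")
  if (alpha0 <= 0) stop("alpha0 must be positive")
  n <- nrow(log_evidence); K <- ncol(log_evidence)
  models <- colnames(log_evidence) %||% paste0("M", seq_len(K))
  alpha <- rep(alpha0, K)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    lu <- log_evidence +
      matrix(digamma(alpha) - digamma(sum(alpha)), n, K, byrow = TRUE)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged)
    warning("BMS did not converge within ", max_iter, " iterations")
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(rgamma(n_mc_samples * K, shape = rep(alpha, each = n_mc_samples)),
                  n_mc_samples, K)
  xp <- tabulate(max.col(draws, ties.method = "first"), K) / n_mc_samples
  structure(list(
    dirichlet_alpha = setNames(alpha, models),
    expected_freq = setNames(alpha / sum(alpha), models),
    exceedance_prob = setNames(xp, models),
    converged = converged, n_iter = iter,
    n_subjects = n, alpha0 = alpha0, n_mc_samples = n_mc_samples
  ), class = "tl_bms")
}

#' @export
print.tl_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection (", x$n_subjects,
      " subjects)\n", sep = "")
  out <- rbind(`Dirichlet alpha` = x$dirichlet_alpha,
               `expected freq` = x$expected_freq,
               `exceedance prob` = x$exceedance_prob)
  print(round(out, 4))
  if (!x$converged) cat("warning: variational iteration did not converge\n")
  invisible(x)
}

#' Full fixed- plus random-effects comparison from a BIC table
#'
#' Convenience wrapper combining [fixed_effects_compare()] and
#' [bms_random_effects()] on the same subject x model BIC table.
#'
#' @inheritParams fixed_effects_compare
#' @inheritParams bms_random_effects
#' @return object of class `tl_comparison` with elements `bic_sums`,
#'   `delta_vs_worst`, `dirichlet_alpha`, `expected_freq`,
#'   `exceedance_prob`, `bms`.
#' @export
compare_models <- function(bic_table, alpha0 = 1, n_mc_samples = 1e6,
                           seed = NULL) {
  ffx <- fixed_effects_compare(bic_table)
  bms <- bms_random_effects(bic_to_log_evidence(as.matrix(bic_table)),
                            alpha0 = alpha0, n_mc_samples = n_mc_samples,
                            seed = seed)
  structure(c(ffx, list(dirichlet_alpha = bms$dirichlet_alpha,
                        expected_freq = bms$expected_freq,
                        exceedance_prob = bms$exceedance_prob, bms = bms)),
            class = "tl_comparison")
}

#' @export
print.tl_comparison <- function(x, ...) {
  cat("Model comparison\n  fixed effects (delta BIC vs worst; larger = better):\n")
  print(round(x$delta_vs_worst, 2))
  cat("  random effects exceedance probabilities:\n")
  print(round(x$exceedance_prob, 4))
  invisible(x)
}
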