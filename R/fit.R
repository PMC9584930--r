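# ---- run-data plumbing -------------------------------------------------

# Normalize participant runs to a common list form. Accepts a list of
# data.frames with columns item, response, feedback (trial optional; row
# order is trial order), or a single such data.frame (one run).
as_run_list <- function(runs, design) {
  if (is.data.frame(runs)) runs <- list(runs)
  lapply(runs, function(r) {
    stopifnot(all(c("item", "feedback") %in% names(r)))
    if (!"response" %in% names(r)) r$response <- NA_real_
    if ("trial" %in% names(r)) r <- r[order(r$trial), ]
    if (anyDuplicated(r$item)) stop("duplicate items within a run")
    list(items = item_index(as.character(r$item), design) - 1L,
         feedback = as.numeric(r$feedback),
         response = as.numeric(r$response))
  })
}

# parameter bounds; b0/b1 are unbounded (regression coefficients)
param_bounds <- function(spec, design) {
  lo <- hi <- setNames(numeric(length(spec$param_names)), spec$param_names)
  for (p in spec$param_names) {
    b <- switch(p,
      alpha = , alpha_pos = , alpha_neg = , gamma = c(0, 1),
      start = c(design$scale_min, design$scale_max),
      b0 = , b1 = c(-Inf, Inf))
    lo[p] <- b[1]; hi[p] <- b[2]
  }
  list(lower = lo, upper = hi)
}

project_params <- function(par, bounds) {
  pmin(bounds$upper, pmax(bounds$lower, par))
}

# midpoint initialization: 0.5 for unit-interval parameters, the scale
# midpoint for scale-unit parameters, (0.5, mid) for the regression slope
# and intercept
param_init <- function(spec, design) {
  mid <- (design$scale_min + design$scale_max) / 2
  setNames(vapply(spec$param_names, function(p) switch(p,
    alpha = , alpha_pos = , alpha_neg = , gamma = , b1 = 0.5,
    start = , b0 = mid), numeric(1)), spec$param_names)
}

#' Sum of squared prediction errors of a model on participant data
#'
#' Evaluates a parameter vector: the model is played through every run
#' (state reset per run, updates driven by the shown feedback) and squared
#' deviations between the model's predictions and the participant's
#' responses are summed over all non-missing trials. Parameters outside
#' their bounds are projected onto the bounds before evaluation, so an
#' unconstrained simplex search can be used.
#'
#' @param params named numeric vector in the order of `spec$param_names`.
#' @param spec a [model_spec()].
#' @param runs a data.frame or list of data.frames with columns `item`,
#'   `response` (NA = missing), `feedback`; row order is trial order.
#' @param design a [build_design()] object.
#' @param rp,sim reference point / similarity matrix as the model requires.
#' @return the scalar SSE (scale units squared).
#' @export
sse_objective <- function(params, spec, runs, design, rp = NULL, sim = NULL) {
  run_list <- as_run_list(runs, design)
  if (!any(vapply(run_list, function(r) any(!is.na(r$response)), logical(1))))
    stop("all trials are missing; nothing to fit")
  bounds <- param_bounds(spec, design)
  sse_eval(project_params(setNames(as.numeric(params), spec$param_names),
                          bounds),
           spec, run_list, design, rp, sim)
}

# internal: evaluate SSE on preprocessed runs, params already projected
sse_eval <- function(params, spec, run_list, design, rp, sim) {
  params <- as.list(params)
  model <- as.integer(substring(spec$model_id, 2))
  a_pos <- a_neg <- 0
  if (model > 1) {
    if (spec$dual_alpha) { a_pos <- params$alpha_pos; a_neg <- params$alpha_neg }
    else a_pos <- a_neg <- params$alpha
  }
  rp_vec <- if (is.null(rp)) numeric(length(design$items)) else unname(rp[design$items])
  sim_mat <- if (is.null(sim)) matrix(0, 0, 0) else sim[design$items, design$items]
  sse_core_cpp(model, a_pos, a_neg, params$gamma %||% 0, params$start %||% 0,
               params$b0 %||% 0, params$b1 %||% 0,
               lapply(run_list, `[[`, "items"),
               lapply(run_list, `[[`, "feedback"),
               lapply(run_list, `[[`, "response"),
               match(design$factor_of, design$factors) - 1L,
               rp_vec, sim_mat, length(design$items), length(design$factors))
}

#' Bayesian information criterion for a least-squares fit
#'
#' `BIC = n * ln(SSE / n) + k * ln(n)` with `n` the number of fitted trials
#' and `k` the number of free parameters; lower is better. An SSE of exactly
#' zero (reachable only on noise-free synthetic data) is floored at 1e-12 to
#' keep the criterion finite.
#'
#' @param sse sum of squared errors (>= 0).
#' @param n number of trials used (>= 1).
#' @param k number of free parameters.
#' @return scalar BIC.
#' @examples
#' compute_bic(240, 240, 3)  # 3 * log(240)
#' @export
compute_bic <- function(sse, n, k) {
  if (n < 1) stop("n must be positive")
  if (sse < 0) stop("sse must be non-negative")
  n * log(max(sse, 1e-12) / n) + k * log(n)
}

#' Fit a learning model to one participant's runs
#'
#' Minimizes the sum of squared prediction errors over all runs and
#' non-missing trials with a Nelder-Mead simplex search started from the
#' parameter midpoints (0.5 for alpha and gamma, the scale midpoint for the
#' starting value). Bounds are enforced by projecting parameters inside the
#' objective. Model M1 is a linear regression of responses on the reference
#' point and is fitted exactly by ordinary least squares by default
#' (an equivalent minimizer; `options$m1_method = "nelder-mead"` forces the
#' simplex path).
#'
#' @inheritParams sse_objective
#' @param options list: `reltol` (default 1e-6), `maxit` (default 2000
#'   objective evaluations per simplex pass), `n_restarts` (default 3:
#'   the simplex is restarted from its own solution until no further
#'   improvement, guarding against premature collapse), `m1_method`
#'   ("ols" or "nelder-mead"), `n_starts` (default 1; extra random starting
#'   points for robustness studies), `oob_penalty` (weight of the quadratic
#'   out-of-bounds penalty).
#' @return object of class `tl_fit` with the fitted `params` (within
#'   bounds), `sse`, `n_trials_used`, `bic`, `converged`, `n_obj_evals`,
#'   plus the spec, design, data and knowledge structures used (so that
#'   `predict`, `residuals` and `simulate` methods work).
#' @examples
#' d <- build_design("exp2")
#' pop <- generate_population(d, n_raters = 150, seed = 1)
#' sim <- derive_similarity(pop); rp <- derive_reference_point(pop)
#' prof <- sample_profiles(pop, 4, seed = 2)
#' spec <- model_spec("M2")
#' runs <- lapply(prof, function(p)
#'   simulate_agent(spec, c(alpha = 0.3, start = 4), sample(d$items), p, d,
#'                  noise_sd = 0.5))
#' fit <- fit_model(spec, runs, d)
#' coef(fit)
#' @export
fit_model <- function(spec, runs, design, rp = NULL, sim = NULL,
                      options = list()) {
  stopifnot(inherits(spec, "tl_model_spec"), inherits(design, "tl_design"))
  opts <- utils::modifyList(
    list(reltol = 1e-6, maxit = 2000, m1_method = "ols", n_starts = 1,
         n_restarts = 3, oob_penalty = 1e3),
    options)
  run_list <- as_run_list(runs, design)
  n_used <- sum(vapply(run_list, function(r) sum(!is.na(r$response)),
                       integer(1)))
  if (n_used == 0) stop("all trials are missing; nothing to fit")
  if (spec$uses_rp && is.null(rp))
    stop(spec$model_id, " needs a reference point")
  if (spec$uses_sim && is.null(sim))
    stop(spec$model_id, " needs a similarity matrix")
  bounds <- param_bounds(spec, design)

  if (spec$model_id == "M1" && opts$m1_method == "ols") {
    rp_vec <- unname(rp[design$items])
    x <- unlist(lapply(run_list, function(r) rp_vec[r$items + 1L]))
    y <- unlist(lapply(run_list, `[[`, "response"))
    ok <- !is.na(y)
    ols <- lm(y[ok] ~ x[ok])
    params <- setNames(as.numeric(coef(ols)), c("b0", "b1"))
    if (anyNA(params)) params[is.na(params)] <- 0  # constant rp: slope moot
    sse <- sum(residuals(ols)^2)
    res <- list(params = params, sse = sse, converged = TRUE, evals = 1L)
  } else {
    # out-of-bounds parameters are projected onto the bounds before the
    # model is evaluated; a quadratic penalty on the projection distance
    # keeps the surface sloped outside the box so the simplex cannot
    # degenerate on a flat plateau at a bound
    obj <- function(par) {
      par <- setNames(par, spec$param_names)
      proj <- project_params(par, bounds)
      excess <- par - proj
      sse_eval(proj, spec, run_list, design, rp, sim) +
        opts$oob_penalty * sum(excess * excess)
    }
    init <- param_init(spec, design)
    best <- NULL
    for (s in seq_len(opts$n_starts)) {
      start_par <- if (s == 1) init else {
        lo <- pmax(bounds$lower, design$scale_min - 10)
        hi <- pmin(bounds$upper, design$scale_max + 10)
        setNames(runif(length(init), lo, hi), spec$param_names)
      }
      opt <- optim(start_par, obj, method = "Nelder-Mead",
                   control = list(maxit = opts$maxit, reltol = opts$reltol))
      # the simplex can collapse prematurely in curved valleys; restarting
      # it from the incumbent until no further improvement is the standard
      # remedy (still a single initialization point)
      for (r in seq_len(opts$n_restarts)) {
        opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = opts$maxit,
                                     reltol = opts$reltol))
        opt2$counts <- opt$counts + opt2$counts
        improved <- opt$value - opt2$value >
          opts$reltol * (abs(opt$value) + opts$reltol)
        if (opt2$value <= opt$value) opt <- opt2
        if (!improved) break
      }
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    params <- project_params(setNames(best$par, spec$param_names), bounds)
    res <- list(params = params, sse = best$value,
                converged = best$convergence == 0,
                evals = unname(best$counts["function"]))
  }

  structure(list(
    spec = spec, params = res$params, sse = res$sse,
    n_trials_used = n_used,
    bic = compute_bic(res$sse, n_used, spec$k_free),
    converged = res$converged, n_obj_evals = res$evals,
    design = design, rp = rp, sim = sim, runs = runs
  ), class = "tl_fit")
}

# ---- tl_fit methods ----------------------------------------------------

#' @export
print.tl_fit <- function(x, ...) {
  cat("Fitted trait-learning model ", x$spec$model_id,
      if (x$spec$dual_alpha) " (dual alpha)", "\n", sep = "")
  print(round(x$params, 4))
  cat(sprintf("SSE %.4f over %d trials; BIC %.4f; %s in %d evaluations\n",
              x$sse, x$n_trials_used, x$bic,
              if (x$converged) "converged" else "NOT converged",
              x$n_obj_evals))
  invisible(x)
}

#' @export
coef.tl_fit <- function(object, ...) object$params

#' @export
summary.tl_fit <- function(object, ...) {
  preds <- predict(object)
  per_run <- vapply(preds, function(p) {
    ok <- !is.na(p$response)
    c(sse = sum((p$response[ok] - p$prediction[ok])^2), n = sum(ok))
  }, numeric(2))
  out <- list(fit = object, per_run = t(per_run),
              rmse = sqrt(object$sse / object$n_trials_used))
  class(out) <- "summary.tl_fit"
  out
}

#' @export
print.summary.tl_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("RMSE per trial: %.4f\n", x$rmse))
  cat("Per-run SSE:\n")
  print(round(x$per_run, 4))
  invisible(x)
}

#' Predictions of a fitted model
#'
#' Replays the fitted model through runs (the fitted runs by default) and
#' returns its trial-by-trial predictions.
#'
#' @param object a `tl_fit`.
#' @param runs optional new runs in the [fit_model()] format.
#' @param ... unused.
#' @return list of data.frames (one per run) with `trial`, `item`,
#'   `prediction`, `feedback`, `pe`, `response`.
#' @export
predict.tl_fit <- function(object, runs = NULL, ...) {
  runs <- runs %||% object$runs
  if (is.data.frame(runs)) runs <- list(runs)
  lapply(runs, function(r) {
    fb <- setNames(as.numeric(r$feedback), as.character(r$item))
    out <- run_model(object$spec, object$params, as.character(r$item), fb,
                     object$design, object$rp, object$sim)
    out$response <- if ("response" %in% names(r)) as.numeric(r$response) else NA_real_
    out
  })
}

#' @export
residuals.tl_fit <- function(object, ...) {
  preds <- predict(object)
  unlist(lapply(preds, function(p) p$response - p$prediction))
}

#' Simulate agent responses from a fitted model
#'
#' @param object a `tl_fit`.
#' @param nsim number of simulated sessions.
#' @param seed optional integer seed.
#' @param noise_sd response noise SD.
#' @param discretize round and cap responses to the scale?
#' @param ... unused.
#' @return list of `nsim` sessions, each a list of per-run data.frames from
#'   [simulate_agent()].
#' @export
simulate.tl_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 1,
                            discretize = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simplify = FALSE, {
    lapply(object$runs, function(r) {
      fb <- setNames(as.numeric(r$feedback), as.character(r$item))
      simulate_agent(object$spec, object$params,
                     sample(object$design$items), fb, object$design,
                     noise_sd = noise_sd, discretize = discretize,
                     rp = object$rp, sim = object$sim)
    })
  })
}

#' Diagnostic plot for a fitted model
#'
#' Mean absolute prediction error per trial position for the participant's
#' responses and for the model's predictions, with least-squares trend
#' lines.
#'
#' @param x a `tl_fit`.
#' @param ... passed to [plot()].
#' @export
plot.tl_fit <- function(x, ...) {
  preds <- predict(x)
  nt <- max(vapply(preds, nrow, integer(1)))
  resp_pe <- rowMeans(sapply(preds, function(p)
    abs(p$feedback - p$response)[seq_len(nt)]), na.rm = TRUE)
  model_pe <- rowMeans(sapply(preds, function(p) abs(p$pe)[seq_len(nt)]))
  plot(seq_len(nt), resp_pe, type = "p", pch = 16, col = "grey40",
       xlab = "trial", ylab = "mean |PE|", ...)
  points(seq_len(nt), model_pe, pch = 1, col = "firebrick")
  abline(lm(resp_pe ~ seq_len(nt)), col = "grey40", lty = 2)
  abline(lm(model_pe ~ seq_len(nt)), col = "firebrick", lty = 2)
  legend("topright", c("responses", "model"), pch = c(16, 1),
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
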