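# draw one generating parameter vector: unit-interval parameters uniform on
# [low, high], scale-unit parameters (starting value, intercept) uniform on
# the rating scale
draw_params <- function(spec, design, low, high) {
  setNames(vapply(spec$param_names, function(p) switch(p,
    alpha = , alpha_pos = , alpha_neg = , gamma = , b1 = runif(1, low, high),
    start = , b0 = runif(1, design$scale_min, design$scale_max)),
    numeric(1)), spec$param_names)
}

# simulate one synthetic participant: noisy agent responses on every profile
# (random trial order per run); responses stay continuous unless discretize
simulate_runs <- function(spec, params, profiles, design, rp, sim,
                          noise_sd = 1, discretize = FALSE) {
  lapply(profiles, function(p) {
    out <- simulate_agent(spec, params, sample(design$items), p, design,
                          noise_sd = noise_sd, discretize = discretize,
                          rp = rp, sim = sim)
    out[, c("trial", "item", "response", "feedback")]
  })
}

#' Parameter recovery study
#'
#' Repeatedly draws generating parameters, simulates noisy agent responses
#' on the design's profiles, refits the same model, and correlates
#' generating with recovered parameter values. High correlations indicate an
#' identifiable model. Unit-interval parameters are drawn uniformly on
#' `[param_low, param_high]`; the starting value (and M1's intercept) are
#' drawn uniformly on the rating scale.
#'
#' @param spec a [model_spec()].
#' @param design a [build_design()] object.
#' @param profiles list of profiles (named feedback vectors or
#'   `tl_profile`s).
#' @param rp,sim knowledge structures as the model requires.
#' @param n_reps number of replicates (>= 2).
#' @param param_low,param_high draw bounds for unit-interval parameters.
#' @param noise_sd response noise SD (default 1: standard normal noise).
#' @param seed optional integer seed (the whole study is reproducible).
#' @param discretize round simulated responses to the scale? Default FALSE:
#'   continuous noisy responses are fitted.
#' @param options fitting options passed to [fit_model()].
#' @return object of class `tl_recovery`: list with `correlations` (named
#'   per parameter; NA with a flag when a parameter column is constant),
#'   `generating` and `recovered` (n_reps x k matrices), `n_reps`,
#'   `noise_sd`, `param_range`, `seed`.
#' @export
parameter_recovery <- function(spec, design, profiles, rp = NULL, sim = NULL,
                               n_reps = 200, param_low = 0, param_high = 1,
                               noise_sd = 1, seed = NULL, discretize = FALSE,
                               options = list()) {
  stopifnot(n_reps >= 2)
  if (param_low > param_high) stop("param_low must not exceed param_high")
  if (!is.null(seed)) set.seed(seed)
  k <- spec$k_free
  gen <- rec <- matrix(NA_real_, n_reps, k,
                       dimnames = list(NULL, spec$param_names))
  for (i in seq_len(n_reps)) {
    pars <- draw_params(spec, design, param_low, param_high)
    runs <- simulate_runs(spec, pars, profiles, design, rp, sim,
                          noise_sd = noise_sd, discretize = discretize)
    fit <- fit_model(spec, runs, design, rp = rp, sim = sim, options = options)
    gen[i, ] <- pars
    rec[i, ] <- fit$params[spec$param_names]
  }
  cors <- setNames(rep(NA_real_, k), spec$param_names)
  degenerate <- setNames(rep(FALSE, k), spec$param_names)
  for (p in spec$param_names) {
    if (sd(gen[, p]) == 0 || sd(rec[, p]) == 0) degenerate[p] <- TRUE
    else cors[p] <- cor(gen[, p], rec[, p])
  }
  structure(list(correlations = cors, degenerate = degenerate,
                 generating = gen, recovered = rec, n_reps = n_reps,
                 noise_sd = noise_sd,
                 param_range = c(param_low, param_high), seed = seed,
                 spec = spec),
            class = "tl_recovery")
}

#' @export
print.tl_recovery <- function(x, ...) {
  cat("Parameter recovery for ", x$spec$model_id, ": ", x$n_reps,
      " replicates, noise SD ", x$noise_sd, "\n", sep = "")
  cat("Generating-vs-recovered Pearson r:\n")
  print(round(x$correlations, 3))
  if (any(x$degenerate))
    cat("constant (undefined) columns:",
        paste(names(x$degenerate)[x$degenerate], collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.tl_recovery <- function(x, ...) {
  k <- ncol(x$generating)
  op <- graphics::par(mfrow = c(1, k)); on.exit(graphics::par(op))
  for (p in colnames(x$generating)) {
    plot(x$generating[, p], x$recovered[, p], pch = 16, cex = 0.6,
         xlab = paste("generating", p), ylab = paste("recovered", p),
         main = sprintf("r = %.3f", x$correlations[p]), ...)
    abline(0, 1, col = "grey60")
  }
  invisible(x)
}

#' Model confusion matrix
#'
#' For each model in the set, repeatedly simulates noisy data (parameters
#' drawn uniformly, standard-normal response noise by default), fits every
#' model in the set to each simulated dataset, and credits the model with
#' the lowest BIC. Rows are the generating models, columns the best-fitting
#' models; ideal recovery is the identity matrix. BIC ties are broken in
#' favour of the lowest model index.
#'
#' @param specs list of [model_spec()]s (>= 2, or a single spec for the
#'   trivial 1x1 case).
#' @inheritParams parameter_recovery
#' @param param_low,param_high draw bounds for unit-interval parameters
#'   (default 0.2-0.8).
#' @return object of class `tl_confusion`: `proportions` (K x K, rows sum
#'   to 1), `counts`, `n_reps`, `noise_sd`, `seed`.
#' @export
confusion_matrix <- function(specs, design, profiles, rp = NULL, sim = NULL,
                             n_reps = 200, param_low = 0.2, param_high = 0.8,
                             noise_sd = 1, seed = NULL, options = list()) {
  stopifnot(n_reps >= 1)
  if (inherits(specs, "tl_model_spec")) specs <- list(specs)
  if (param_low >= param_high) stop("param_low must be below param_high")
  if (!is.null(seed)) set.seed(seed)
  K <- length(specs)
  labels <- vapply(specs, `[[`, character(1), "model_id")
  counts <- matrix(0L, K, K, dimnames = list(generating = labels,
                                             recovered = labels))
  for (g in seq_len(K)) {
    for (i in seq_len(n_reps)) {
      pars <- draw_params(specs[[g]], design, param_low, param_high)
      runs <- simulate_runs(specs[[g]], pars, profiles, design, rp, sim,
                            noise_sd = noise_sd)
      bics <- vapply(specs, function(sp)
        fit_model(sp, runs, design, rp = rp, sim = sim,
                  options = options)$bic, numeric(1))
      win <- which.min(bics)  # first index wins ties
      counts[g, win] <- counts[g, win] + 1L
    }
  }
  structure(list(proportions = counts / n_reps, counts = counts,
                 n_reps = n_reps, noise_sd = noise_sd, seed = seed,
                 param_range = c(param_low, param_high)),
            class = "tl_confusion")
}

#' @export
print.tl_confusion <- function(x, ...) {
  cat("Model confusion matrix (", x$n_reps,
      " simulations per generating model, noise SD ", x$noise_sd, ")\n",
      sep = "")
  print(round(x$proportions, 3))
  cat(sprintf("minimum diagonal: %.1f%%\n", 100 * min(diag(x$proportions))))
  invisible(x)
}

#' Best performing model in the set (task optimality)
#'
#' Fits every model to the profiles' own feedback sequences instead of
#' participant responses: the prediction at each trial is made from the
#' feedback history up to the previous trial, so a model's BIC measures how
#' well its learning strategy solves the task itself. The ranking indicates
#' which strategy is optimal in the set, independent of what participants
#' did.
#'
#' @inheritParams confusion_matrix
#' @param seed optional seed for the random trial orders.
#' @return object of class `tl_best`: list of `tl_fit`s plus a `table`
#'   data.frame (model, sse, bic) sorted by BIC.
#' @export
best_performing <- function(specs, profiles, design, rp = NULL, sim = NULL,
                            seed = NULL, options = list()) {
  if (inherits(specs, "tl_model_spec")) specs <- list(specs)
  if (!length(profiles)) stop("profiles must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  orders <- lapply(profiles, function(p) sample(design$items))
  runs <- mapply(function(p, ord) {
    fb <- if (inherits(p, "tl_profile")) p$feedback else p
    data.frame(trial = seq_along(ord), item = ord,
               response = unname(fb[ord]), feedback = unname(fb[ord]),
               stringsAsFactors = FALSE)
  }, profiles, orders, SIMPLIFY = FALSE)
  fits <- lapply(specs, function(sp)
    fit_model(sp, runs, design, rp = rp, sim = sim, options = options))
  labels <- vapply(specs, `[[`, character(1), "model_id")
  tab <- data.frame(model = labels,
                    sse = vapply(fits, `[[`, numeric(1), "sse"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"))
  tab <- tab[order(tab$bic), ]
  structure(list(fits = setNames(fits, labels), table = tab),
            class = "tl_best")
}

#' @export
print.tl_best <- function(x, ...) {
  cat("Task-optimality ranking (models fitted on profile feedback):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
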