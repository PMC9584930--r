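#' Specify a learning model
#'
#' The five model families differ in granularity and reference-point use:
#' \describe{
#'   \item{M1 (no learning)}{linear regression of predictions on the
#'     reference point, `P = b1 * RP + b0`; free parameters b0, b1.}
#'   \item{M2 (coarse granularity)}{Rescorla-Wagner update of one value per
#'     factor, `P(t+1, F) = P(t, F) + alpha * PE`; free parameters alpha,
#'     starting value.}
#'   \item{M3 (coarse + reference point)}{as M2 but the emitted prediction
#'     blends the current item's reference point with the learned factor
#'     value, `P = gamma * RP + (1 - gamma) * P(F)`, while the factor value
#'     itself accumulates the RW update driven by the blended prediction's
#'     error; free parameters alpha, gamma, starting value.}
#'   \item{M4 (fine granularity)}{one value per item, every item updated in
#'     proportion to its signed correlation with the current item:
#'     `P(t+1, All) = P(t, All) + alpha * PE * SIM`; free parameters alpha,
#'     starting value.}
#'   \item{M5 (fine + reference point)}{as M4 with the reference-point
#'     blend at prediction time, `P = gamma * RP + (1 - gamma) * P(item)`;
#'     free parameters alpha, gamma, starting value.}
#' }
#' With `gamma = 0`, M3 reduces exactly to M2 and M5 to M4; with
#' `gamma = 1` the reference-point models emit the reference point on every
#' trial.
#' Setting `dual_alpha = TRUE` replaces alpha by separate learning rates for
#' negative (`alpha_neg`, applied when PE < 0) and non-negative
#' (`alpha_pos`, PE >= 0) prediction errors, adding one free parameter.
#' `rp_source` records which reference point the model uses (population,
#' stereotype, or the participant's own self-ratings); the equations are
#' identical across sources.
#'
#' @param model_id one of `"M1"` ... `"M5"`.
#' @param rp_source `"none"` (only valid for M2/M4), `"population"`,
#'   `"stereotype"`, or `"self"`.
#' @param dual_alpha logical; separate learning rates for positive and
#'   negative prediction errors (invalid for M1, which does not learn).
#' @return object of class `tl_model_spec` with fields `model_id`,
#'   `rp_source`, `dual_alpha`, `granularity`, `uses_rp`, `uses_sim`,
#'   `param_names`, `k_free`.
#' @examples
#' model_spec("M5")
#' model_spec("M3", rp_source = "stereotype", dual_alpha = TRUE)
#' @export
model_spec <- function(model_id = c("M1", "M2", "M3", "M4", "M5"),
                       rp_source = NULL, dual_alpha = FALSE) {
  model_id <- match.arg(model_id)
  uses_rp <- model_id %in% c("M1", "M3", "M5")
  if (is.null(rp_source)) rp_source <- if (uses_rp) "population" else "none"
  rp_source <- match.arg(rp_source, c("none", "population", "stereotype", "self"))
  if (uses_rp && rp_source == "none")
    stop(model_id, " requires a reference-point source")
  if (!uses_rp && rp_source != "none")
    stop(model_id, " does not use a reference point; rp_source must be 'none'")
  if (dual_alpha && model_id == "M1")
    stop("M1 has no learning rate; dual_alpha is not applicable")
  param_names <- switch(model_id,
    M1 = c("b0", "b1"),
    M2 = , M4 = c("alpha", "start"),
    M3 = , M5 = c("alpha", "gamma", "start"))
  if (dual_alpha)
    param_names <- c("alpha_pos", "alpha_neg", setdiff(param_names, "alpha"))
  structure(list(
    model_id = model_id,
    rp_source = rp_source,
    dual_alpha = isTRUE(dual_alpha),
    granularity = switch(model_id, M1 = "none", M2 = , M3 = "coarse",
                         M4 = , M5 = "fine"),
    uses_rp = uses_rp,
    uses_sim = model_id %in% c("M4", "M5"),
    param_names = param_names,
    k_free = length(param_names)
  ), class = "tl_model_spec")
}

#' @export
print.tl_model_spec <- function(x, ...) {
  lab <- switch(x$model_id,
    M1 = "no learning (reference-point regression)",
    M2 = "coarse granularity RW",
    M3 = "coarse granularity RW + reference point",
    M4 = "fine granularity RW",
    M5 = "fine granularity RW + reference point")
  cat(x$model_id, ": ", lab, "\n", sep = "")
  if (x$uses_rp) cat("  reference point:", x$rp_source, "\n")
  if (x$dual_alpha) cat("  dual learning rates (alpha+ / alpha-)\n")
  cat("  free parameters (k = ", x$k_free, "): ",
      paste(x$param_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Prediction error
#'
#' The learning signal of all Rescorla-Wagner updates: feedback minus the
#' model's prediction on the current trial.
#'
#' @param feedback,prediction finite numeric values (vectorized).
#' @return `feedback - prediction`.
#' @examples
#' compute_pe(7, 5)  # 2
#' @export
compute_pe <- function(feedback, prediction) {
  stopifnot(all(is.finite(feedback)), all(is.finite(prediction)))
  feedback - prediction
}

#' Initialize the model's value state
#'
#' Coarse models hold one value per factor, fine models one value per item;
#' all entries start at the free starting value. M1 holds no state.
#'
#' @param spec a [model_spec()].
#' @param params named parameter vector/list (needs `start` for M2-M5).
#' @param design a [build_design()] object.
#' @return named numeric state vector (length 0 for M1).
#' @export
init_state <- function(spec, params, design) {
  params <- as.list(params)
  switch(spec$granularity,
    none = setNames(numeric(0), character(0)),
    coarse = setNames(rep(params$start, length(design$factors)),
                      design$factors),
    fine = setNames(rep(params$start, length(design$items)), design$items))
}

#' Model prediction for one item
#'
#' M1 returns `rp[item] * b1 + b0`; M2/M4 return the stored value of the
#' item's factor / of the item; the reference-point learners M3/M5 return
#' the blend `gamma * rp[item] + (1 - gamma) * stored value`. No clipping is
#' applied.
#'
#' @param state state vector from [init_state()] / [update_state()].
#' @inheritParams init_state
#' @param item item id.
#' @param rp named reference-point vector (M1/M3/M5).
#' @return scalar prediction in scale units.
#' @export
predict_trial <- function(state, spec, params, item, design, rp = NULL) {
  item_index(item, design)  # validates the item
  params <- as.list(params)
  if (spec$uses_rp && is.null(rp))
    stop(spec$model_id, " needs a reference point")
  value <- switch(spec$granularity,
    none = return(unname(rp[item] * params$b1 + params$b0)),
    coarse = state[design$factor_of[item]],
    fine = state[item])
  if (spec$model_id %in% c("M3", "M5")) {
    g <- params$gamma
    unname(g * rp[item] + (1 - g) * value)
  } else unname(value)
}

#' Apply one trial's learning update
#'
#' Applies the Rescorla-Wagner increment to the stored values: coarse models
#' (M2/M3) add `alpha * pe` to the current item's factor value; fine models
#' (M4/M5) add `alpha * pe * sim[, item]` to every item's value. M1 does not
#' learn. With dual learning rates, `alpha_neg` is used when `pe < 0` and
#' `alpha_pos` when `pe >= 0`. The prediction error must come from the
#' trial's emitted prediction (for M3/M5 the reference-point blend, see
#' [predict_trial()]). State values are never clipped to the rating scale;
#' the equations are linear and clipping happens only when discretized agent
#' responses are emitted.
#'
#' @inheritParams predict_trial
#' @param pe prediction error from the current trial's emitted prediction.
#' @param sim signed item x item similarity matrix (fine models);
#'   `sim[, item]` is the correlation of every item with the current item.
#' @return the updated state vector.
#' @export
update_state <- function(state, spec, params, item, pe, design, rp = NULL,
                         sim = NULL) {
  params <- as.list(params)
  if (spec$model_id == "M1") return(state)
  alpha <- if (spec$dual_alpha) {
    if (pe < 0) params$alpha_neg else params$alpha_pos
  } else params$alpha
  if (spec$uses_sim && is.null(sim)) stop(spec$model_id, " needs a similarity matrix")
  if (spec$granularity == "coarse") {
    f <- design$factor_of[item]
    state[f] <- state[f] + alpha * pe
    state
  } else {
    state + alpha * pe * sim[, item]
  }
}

# pack parameters and call the compiled trial loop; items is a character
# vector (trial order), feedback a named per-item vector
run_core_wrapper <- function(spec, params, trial_order, feedback, design,
                             rp = NULL, sim = NULL) {
  params <- as.list(params)
  model <- as.integer(substring(spec$model_id, 2))
  if (spec$uses_rp && is.null(rp))
    stop(spec$model_id, " needs a reference point")
  if (spec$uses_sim && is.null(sim))
    stop(spec$model_id, " needs a similarity matrix")
  a_pos <- a_neg <- 0
  if (model > 1) {
    if (spec$dual_alpha) { a_pos <- params$alpha_pos; a_neg <- params$alpha_neg }
    else a_pos <- a_neg <- params$alpha
  }
  items_idx <- item_index(trial_order, design)
  fb <- unname(feedback[trial_order])
  rp_vec <- if (is.null(rp)) numeric(length(design$items)) else unname(rp[design$items])
  sim_mat <- if (is.null(sim)) matrix(0, 0, 0) else sim[design$items, design$items]
  run_core_cpp(model, a_pos, a_neg,
               params$gamma %||% 0, params$start %||% 0,
               params$b0 %||% 0, params$b1 %||% 0,
               items_idx - 1L, fb,
               match(design$factor_of, design$factors) - 1L,
               rp_vec, sim_mat,
               length(design$items), length(design$factors))
}

#' Run a model through one learning run
#'
#' Plays a model through a run: for each trial it emits the prediction for
#' the presented item, computes the prediction error against the profile's
#' feedback, and applies the model's update. The state is freshly
#' initialized (models never carry information across profiles).
#'
#' @inheritParams init_state
#' @param trial_order character vector: a permutation of the design's items.
#' @param feedback named per-item feedback vector (a profile's self-ratings),
#'   or a `tl_profile`.
#' @param rp named reference-point vector (M1/M3/M5).
#' @param sim item x item similarity matrix (M4/M5).
#' @return data.frame with columns `trial`, `item`, `prediction`,
#'   `feedback`, `pe`.
#' @examples
#' d <- build_design("exp2")
#' pop <- generate_population(d, n_raters = 100, seed = 1)
#' pr <- sample_profiles(pop, 1, seed = 2)[[1]]
#' seq1 <- run_model(model_spec("M2"), c(alpha = 0.4, start = 4.5),
#'                   sample(d$items), pr, d)
#' head(seq1)
#' @export
run_model <- function(spec, params, trial_order, feedback, design,
                      rp = NULL, sim = NULL) {
  stopifnot(inherits(spec, "tl_model_spec"), inherits(design, "tl_design"))
  if (inherits(feedback, "tl_profile")) feedback <- feedback$feedback
  if (anyDuplicated(trial_order))
    stop("trial_order contains duplicate items")
  if (length(trial_order) != length(design$items) ||
      !setequal(trial_order, design$items))
    stop("trial_order must be a permutation of the design's items")
  pred <- run_core_wrapper(spec, params, trial_order, feedback, design, rp, sim)
  fb <- unname(feedback[trial_order])
  data.frame(trial = seq_along(trial_order), item = trial_order,
             prediction = pred, feedback = fb, pe = fb - pred,
             stringsAsFactors = FALSE)
}

#' Simulate a noisy agent on one run
#'
#' Runs the model ([run_model()]) and emits responses as the model's
#' noise-free predictions plus Gaussian noise. The agent's internal
#' prediction errors use the noise-free predictions; noise only perturbs the
#' emitted responses. With `discretize = TRUE` responses are rounded and
#' capped to the rating scale.
#'
#' @inheritParams run_model
#' @param noise_sd response noise standard deviation (>= 0).
#' @param discretize round and cap responses to the scale?
#' @param seed optional integer seed.
#' @return data.frame as [run_model()] plus a `response` column.
#' @export
simulate_agent <- function(spec, params, trial_order, feedback, design,
                           noise_sd = 1, discretize = FALSE,
                           rp = NULL, sim = NULL, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- run_model(spec, params, trial_order, feedback, design, rp, sim)
  resp <- out$prediction + rnorm(nrow(out), 0, noise_sd)
  if (discretize) resp <- round_cap(resp, design)
  out$response <- resp
  out
}
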