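test_that("sse_objective sums squared errors over non-missing trials", {
  d <- build_design(config = list(items = c("a", "b"),
                                  factor_of = c("F", "F"),
                                  scale_min = 1, scale_max = 8,
                                  n_profiles = 1))
  rp <- c(a = 4, b = 5)
  run <- data.frame(item = c("a", "b"), response = c(6, 5), feedback = c(6, 5))
  # M1 with b1 = 1, b0 = 0 predicts (4, 5): SSE = 2^2 + 0^2
  expect_equal(sse_objective(c(b0 = 0, b1 = 1), model_spec("M1"), run, d, rp), 4)
  # responses equal to the predictions give zero
  run2 <- data.frame(item = c("a", "b"), response = c(4, 5), feedback = c(6, 5))
  expect_equal(sse_objective(c(0, 1), model_spec("M1"), run2, d, rp), 0)
  # missing responses are excluded
  run3 <- run; run3$response[1] <- NA
  expect_equal(sse_objective(c(0, 1), model_spec("M1"), run3, d, rp), 0)
  run4 <- run; run4$response <- NA_real_
  expect_error(sse_objective(c(0, 1), model_spec("M1"), run4, d, rp),
               "all trials are missing")
})

test_that("sse_objective equals a brute-force oracle on random data", {
  d <- tiny_design()
  rp <- tiny_rp(d); sim <- tiny_sim(d); fb <- tiny_profile(d)
  set.seed(17)
  for (mid in c("M2", "M3", "M4", "M5")) {
    spec <- model_spec(mid)
    pars <- setNames(runif(spec$k_free), spec$param_names)
    pars["start"] <- runif(1, 1, 8)
    runs <- lapply(1:3, function(i) {
      ord <- sample(d$items)
      data.frame(item = ord, response = runif(6, 1, 8),
                 feedback = unname(fb[ord]))
    })
    want <- sum(sapply(runs, function(r) {
      pred <- oracle_run(mid, pars, r$item, fb, d, rp = rp, sim = sim)
      sum((r$response - pred)^2)
    }))
    expect_equal(sse_objective(pars, spec, runs, d, rp, sim), want,
                 tolerance = 1e-10)
  }
})

test_that("BIC follows n*ln(SSE/n) + k*ln(n)", {
  expect_equal(compute_bic(240, 240, 3), 3 * log(240))
  expect_equal(compute_bic(100, 100, 2), 2 * log(100))
  expect_equal(compute_bic(50, 120, 3) - compute_bic(50, 120, 2), log(120))
  # monotone in k at fixed sse, n
  expect_true(all(diff(sapply(1:5, function(k) compute_bic(77, 60, k))) > 0))
  # zero SSE stays finite via the floor
  expect_true(is.finite(compute_bic(0, 240, 3)))
  expect_error(compute_bic(10, 0, 2), "positive")
  expect_error(compute_bic(-1, 10, 2), "non-negative")
})

test_that("M1 ordinary least squares is exact and agrees with the simplex", {
  d <- tiny_design()
  rp <- tiny_rp(d)
  runs <- lapply(1:2, function(i) {
    ord <- sample(d$items)
    data.frame(item = ord, response = 2 * unname(rp[ord]) + 1,
               feedback = unname(tiny_profile(d)[ord]))
  })
  f <- fit_model(model_spec("M1"), runs, d, rp = rp)
  expect_equal(unname(f$params), c(1, 2), tolerance = 1e-8)
  expect_lt(f$sse, 1e-12)
  # noisy data: OLS and Nelder-Mead land on the same optimum
  set.seed(4)
  runs2 <- lapply(runs, function(r) {
    r$response <- r$response + rnorm(nrow(r)); r })
  f_ols <- fit_model(model_spec("M1"), runs2, d, rp = rp)
  f_nm <- fit_model(model_spec("M1"), runs2, d, rp = rp,
                    options = list(m1_method = "nelder-mead",
                                   reltol = 1e-10, maxit = 5000))
  expect_equal(f_ols$sse, f_nm$sse, tolerance = 1e-6)
})

test_that("fitting the generating model to noise-free data recovers it", {
  s <- build_surrogate("exp2", seed = 6, n_raters = 80)
  for (mid in c("M2", "M3", "M4", "M5")) {
    spec <- model_spec(mid)
    pars <- c(alpha = 0.3, gamma = 0.55, start = 4)[spec$param_names]
    set.seed(20)
    runs <- lapply(s$profiles, function(p) {
      r <- simulate_agent(spec, pars, sample(s$design$items), p, s$design,
                          noise_sd = 0, rp = s$rp, sim = s$sim)
      r$response <- r$prediction
      r[, c("item", "response", "feedback")]
    })
    f <- fit_model(spec, runs, s$design, rp = s$rp, sim = s$sim)
    expect_lt(f$sse, 1e-6)
    expect_lt(abs(f$params[["alpha"]] - pars[["alpha"]]), 0.02)
    expect_equal(f$n_trials_used, 240)
    expect_equal(f$bic, compute_bic(f$sse, 240, spec$k_free))
    # the minimizer cannot be worse than its initialization
    init <- c(alpha = 0.5, gamma = 0.5,
              start = 4.5)[seq_len(spec$k_free)]
    names(init) <- spec$param_names
    expect_lte(f$sse,
               sse_objective(init, spec, runs, s$design, s$rp, s$sim))
  }
})

test_that("fit results expose working S3 methods", {
  s <- build_surrogate("exp2", seed = 16, n_raters = 60)
  spec <- model_spec("M2")
  set.seed(2)
  runs <- lapply(s$profiles, function(p) {
    r <- simulate_agent(spec, c(alpha = 0.4, start = 3), sample(s$design$items),
                        p, s$design, noise_sd = 0.5)
    r[, c("item", "response", "feedback")]
  })
  f <- fit_model(spec, runs, s$design)
  expect_s3_class(f, "tl_fit")
  expect_named(coef(f), c("alpha", "start"))
  expect_output(print(f), "SSE")
  preds <- predict(f)
  expect_length(preds, 4)
  expect_equal(sum(residuals(f)^2), f$sse, tolerance = 1e-8)
  sims <- simulate(f, nsim = 2, seed = 3, discretize = TRUE)
  expect_length(sims, 2)
  expect_true(all(sims[[1]][[1]]$response %in% 1:8))
  sm <- summary(f)
  expect_equal(sum(sm$per_run[, "sse"]), f$sse, tolerance = 1e-8)
})

test_that("parameters outside bounds are projected before evaluation", {
  d <- tiny_design()
  fb <- tiny_profile(d)
  run <- data.frame(item = d$items, response = runif(6, 1, 8),
                    feedback = unname(fb))
  spec <- model_spec("M2")
  expect_equal(sse_objective(c(alpha = 1.7, start = 4), spec, run, d),
               sse_objective(c(alpha = 1, start = 4), spec, run, d))
  expect_equal(sse_objective(c(alpha = 0.5, start = -3), spec, run, d),
               sse_objective(c(alpha = 0.5, start = 1), spec, run, d))
})
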