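test_that("prediction error is feedback minus prediction", {
  expect_equal(compute_pe(7, 5), 2)
  expect_equal(compute_pe(3, 3), 0)
  expect_equal(compute_pe(1, 8), -7)
  expect_error(compute_pe(NA, 1), "finite")
})

test_that("model specs enumerate free parameters correctly", {
  expect_equal(model_spec("M1")$param_names, c("b0", "b1"))
  expect_equal(model_spec("M2")$param_names, c("alpha", "start"))
  expect_equal(model_spec("M3")$k_free, 3)
  expect_equal(model_spec("M5", dual_alpha = TRUE)$k_free, 4)
  expect_error(model_spec("M2", rp_source = "population"), "does not use")
  expect_error(model_spec("M5", rp_source = "none"), "requires")
  expect_error(model_spec("M1", dual_alpha = TRUE), "no learning rate")
})

test_that("single-trial prediction and update follow the model equations", {
  d <- tiny_design()
  rp <- tiny_rp(d); sim <- tiny_sim(d)
  # M1: identity regression
  s1 <- model_spec("M1")
  expect_equal(predict_trial(numeric(0), s1, c(b0 = 0, b1 = 1), "i1", d, rp),
               unname(rp["i1"]))
  # M2: fresh state predicts the starting value, update adds alpha * pe
  s2 <- model_spec("M2")
  st <- init_state(s2, c(alpha = 0.5, start = 4.5), d)
  expect_equal(unname(st), rep(4.5, 2))
  expect_equal(predict_trial(st, s2, c(alpha = 0.5, start = 4.5), "i4", d), 4.5)
  st["A"] <- 4
  st2 <- update_state(st, s2, c(alpha = 0.5, start = 4), "i1", pe = 2, d)
  expect_equal(unname(st2["A"]), 5)
  expect_equal(unname(st2["B"]), unname(st["B"]))  # other factor untouched
  # M3 blend: gamma = 1 predicts the reference point
  s3 <- model_spec("M3")
  expect_equal(predict_trial(init_state(s3, list(start = 2, gamma = 1), d),
                             s3, list(alpha = .3, gamma = 1, start = 2),
                             "i2", d, rp),
               unname(rp["i2"]))
  # M4: update moves item j by alpha * pe * sim[j, item]
  s4 <- model_spec("M4")
  sim2 <- sim; sim2["i5", "i1"] <- 0.5
  st4 <- init_state(s4, c(alpha = 0.4, start = 3), d)
  st4b <- update_state(st4, s4, c(alpha = 0.4, start = 3), "i1", pe = 2, d,
                       sim = sim2)
  expect_equal(unname(st4b["i5"] - st4["i5"]), 0.4 * 2 * 0.5)
})

test_that("run_model matches the independent per-trial oracle", {
  d <- tiny_design()
  rp <- tiny_rp(d); sim <- tiny_sim(d)
  fb <- tiny_profile(d)
  set.seed(99)
  cases <- list(
    list("M1", c(b0 = 0.7, b1 = 0.9), FALSE),
    list("M2", c(alpha = 0.37, start = 2.2), FALSE),
    list("M3", c(alpha = 0.6, gamma = 0.45, start = 7.1), FALSE),
    list("M4", c(alpha = 0.52, start = 5.0), FALSE),
    list("M5", c(alpha = 0.8, gamma = 0.25, start = 1.4), FALSE),
    list("M3", c(alpha_pos = 0.7, alpha_neg = 0.2, gamma = 0.5, start = 4), TRUE),
    list("M5", c(alpha_pos = 0.1, alpha_neg = 0.9, gamma = 0.6, start = 6), TRUE))
  for (cs in cases) {
    spec <- model_spec(cs[[1]], dual_alpha = cs[[3]])
    for (rep in 1:3) {
      ord <- sample(d$items)
      got <- run_model(spec, cs[[2]], ord, fb, d, rp = rp, sim = sim)
      want <- oracle_run(cs[[1]], cs[[2]], ord, fb, d, rp = rp, sim = sim,
                         dual = cs[[3]])
      expect_equal(got$prediction, want, tolerance = 1e-10)
      expect_equal(got$pe, unname(fb[ord]) - want, tolerance = 1e-10)
    }
  }
  # larger design too
  s <- build_surrogate("exp1", seed = 3, n_raters = 100)
  ord <- sample(s$design$items)
  pars <- c(alpha = 0.33, gamma = 0.61, start = 6.6)
  got <- run_model(model_spec("M5"), pars, ord, s$profiles[[1]], s$design,
                   rp = s$rp, sim = s$sim)
  want <- oracle_run("M5", pars, ord, s$profiles[[1]]$feedback, s$design,
                     rp = s$rp, sim = s$sim)
  expect_equal(got$prediction, want, tolerance = 1e-10)
})

test_that("model reduction chain holds exactly", {
  d <- tiny_design()
  rp <- tiny_rp(d); sim <- tiny_sim(d); fb <- tiny_profile(d)
  set.seed(123)
  for (rep in 1:5) {
    ord <- sample(d$items)
    a <- runif(1); s0 <- runif(1, 1, 8)
    # M3 with gamma = 0 is M2; M5 with gamma = 0 is M4
    expect_equal(
      run_model(model_spec("M3"), c(alpha = a, gamma = 0, start = s0),
                ord, fb, d, rp = rp)$prediction,
      run_model(model_spec("M2"), c(alpha = a, start = s0),
                ord, fb, d)$prediction)
    expect_equal(
      run_model(model_spec("M5"), c(alpha = a, gamma = 0, start = s0),
                ord, fb, d, rp = rp, sim = sim)$prediction,
      run_model(model_spec("M4"), c(alpha = a, start = s0),
                ord, fb, d, sim = sim)$prediction)
    # M5 with identity similarity and gamma = 0 is a per-item RW learner
    eye <- diag(length(d$items)); dimnames(eye) <- dimnames(sim)
    m5 <- run_model(model_spec("M5"), c(alpha = a, gamma = 0, start = s0),
                    ord, fb, d, rp = rp, sim = eye)$prediction
    state <- setNames(rep(s0, 6), d$items)
    rw <- numeric(6)
    for (t in 1:6) {
      rw[t] <- state[[ord[t]]]
      state[[ord[t]]] <- state[[ord[t]]] + a * (fb[[ord[t]]] - rw[t])
    }
    expect_equal(m5, rw)
    # alpha = 0: predictions stay at the starting value
    expect_equal(run_model(model_spec("M2"), c(alpha = 0, start = s0),
                           ord, fb, d)$prediction, rep(s0, 6))
    expect_equal(run_model(model_spec("M4"), c(alpha = 0, start = s0),
                           ord, fb, d, sim = sim)$prediction, rep(s0, 6))
    # gamma = 1: the reference point is emitted on every trial
    expect_equal(run_model(model_spec("M5"), c(alpha = a, gamma = 1, start = s0),
                           ord, fb, d, rp = rp, sim = sim)$prediction,
                 unname(rp[ord]))
    # dual learning rates with alpha+ = alpha- reduce to the single rate
    expect_equal(
      run_model(model_spec("M5", dual_alpha = TRUE),
                c(alpha_pos = a, alpha_neg = a, gamma = 0.4, start = s0),
                ord, fb, d, rp = rp, sim = sim)$prediction,
      run_model(model_spec("M5"), c(alpha = a, gamma = 0.4, start = s0),
                ord, fb, d, rp = rp, sim = sim)$prediction)
  }
})

test_that("absolute PE shrinks geometrically under repeated feedback", {
  d <- tiny_design()
  spec <- model_spec("M2")
  for (a in c(0.2, 0.5, 0.8)) {
    params <- c(alpha = a, start = 2)
    state <- init_state(spec, params, d)
    pes <- numeric(8)
    for (t in 1:8) {
      pr <- predict_trial(state, spec, params, "i1", d)
      pes[t] <- compute_pe(7, pr)
      state <- update_state(state, spec, params, "i1", pes[t], d)
    }
    expect_equal(abs(pes[-1]) / abs(pes[-8]), rep(1 - a, 7), tolerance = 1e-12)
  }
})

test_that("simulated agents add noise only to the emitted responses", {
  s <- build_surrogate("exp2", seed = 8, n_raters = 80)
  spec <- model_spec("M3")
  pars <- c(alpha = 0.4, gamma = 0.3, start = 4.5)
  ord <- s$design$items
  noiseless <- simulate_agent(spec, pars, ord, s$profiles[[1]], s$design,
                              noise_sd = 0, rp = s$rp)
  ref <- run_model(spec, pars, ord, s$profiles[[1]], s$design, rp = s$rp)
  expect_equal(noiseless$response, ref$prediction)
  expect_equal(noiseless$pe, ref$pe)  # internal PE is noise-free
  noisy <- simulate_agent(spec, pars, ord, s$profiles[[1]], s$design,
                          noise_sd = 1, discretize = TRUE, rp = s$rp,
                          seed = 5)
  expect_true(all(noisy$response %in% 1:8))
  noisy2 <- simulate_agent(spec, pars, ord, s$profiles[[1]], s$design,
                           noise_sd = 1, discretize = TRUE, rp = s$rp,
                           seed = 5)
  expect_identical(noisy, noisy2)
})

test_that("run_model validates its trial order", {
  d <- tiny_design()
  fb <- tiny_profile(d)
  expect_error(run_model(model_spec("M2"), c(alpha = .5, start = 4),
                         c("i1", "i1", "i2", "i3", "i4", "i5"), fb, d),
               "duplicate")
  expect_error(run_model(model_spec("M2"), c(alpha = .5, start = 4),
                         d$items[1:5], fb, d), "permutation")
})
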