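# Independent pure-R re-implementation of the trial-by-trial model
# equations, written as literal scalar loops. Used as the brute-force
# oracle against the package's compiled trial loop; kept deliberately
# separate from the package internals.
oracle_run <- function(model_id, params, trial_order, feedback, design,
                       rp = NULL, sim = NULL, dual = FALSE) {
  p <- as.list(params)
  items <- design$items
  nt <- length(trial_order)
  pred <- numeric(nt)
  if (model_id == "M1") {
    for (t in seq_len(nt))
      pred[t] <- rp[[trial_order[t]]] * p$b1 + p$b0
    return(pred)
  }
  coarse <- model_id %in% c("M2", "M3")
  has_rp <- model_id %in% c("M3", "M5")
  state <- if (coarse) {
    setNames(rep(p$start, length(design$factors)), design$factors)
  } else setNames(rep(p$start, length(items)), items)
  for (t in seq_len(nt)) {
    it <- trial_order[t]
    f <- design$factor_of[[it]]
    base <- if (coarse) state[[f]] else state[[it]]
    pr <- if (has_rp) p$gamma * rp[[it]] + (1 - p$gamma) * base else base
    pred[t] <- pr
    pe <- feedback[[it]] - pr
    a <- if (dual) { if (pe < 0) p$alpha_neg else p$alpha_pos } else p$alpha
    if (coarse) {
      state[[f]] <- state[[f]] + a * pe
    } else {
      for (j in items) state[[j]] <- state[[j]] + a * pe * sim[j, it]
    }
  }
  pred
}

# small custom design for fast unit tests: 6 items, 2 factors
tiny_design <- function(scale = c(1, 8)) {
  build_design(config = list(
    items = paste0("i", 1:6),
    factor_of = c("A", "A", "A", "B", "B", "B"),
    scale_min = scale[1], scale_max = scale[2], n_profiles = 2,
    valence = c(1, -1, 1, 1, 1, -1)))
}

# hand-made knowledge structures for the tiny design
tiny_sim <- function(design, seed = 1) {
  set.seed(seed)
  n <- length(design$items)
  x <- matrix(rnorm(50 * n), 50, n)
  s <- cor(x + rnorm(50))  # shared rater effect gives nonzero correlations
  dimnames(s) <- list(design$items, design$items)
  diag(s) <- 1
  s
}

tiny_rp <- function(design, seed = 2) {
  set.seed(seed)
  setNames(runif(length(design$items), design$scale_min + 1,
                 design$scale_max - 1), design$items)
}

tiny_profile <- function(design, seed = 3) {
  set.seed(seed)
  setNames(sample(design$scale_min:design$scale_max,
                  length(design$items), replace = TRUE), design$items)
}

# one session table of simulated noisy agents, long format
make_session <- function(n_participants, spec, params, surr, noise_sd = 0.5,
                         seed = 1) {
  set.seed(seed)
  rows <- list()
  for (pid in seq_len(n_participants)) {
    for (r in seq_along(surr$profiles)) {
      run <- simulate_agent(spec, params, sample(surr$design$items),
                            surr$profiles[[r]], surr$design,
                            noise_sd = noise_sd, discretize = TRUE,
                            rp = surr$rp, sim = surr$sim)
      rows[[length(rows) + 1]] <- data.frame(
        participant = paste0("p", pid), run = r, trial = run$trial,
        item = run$item, response = run$response, feedback = run$feedback)
    }
  }
  do.call(rbind, rows)
}
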