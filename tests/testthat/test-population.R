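test_that("generated ratings are integers within scale bounds and reproducible", {
  for (preset in c("exp1", "exp5")) {
    d <- build_design(preset)
    pop <- generate_population(d, n_raters = 80, seed = 5)
    expect_true(all(pop$ratings == round(pop$ratings)))
    expect_true(all(pop$ratings >= d$scale_min & pop$ratings <= d$scale_max))
    pop2 <- generate_population(d, n_raters = 80, seed = 5)
    expect_identical(pop$ratings, pop2$ratings)
  }
  d <- build_design("exp1")
  expect_error(generate_population(d, within_factor_loading = 1.2), "loading")
  expect_error(generate_population(d, n_raters = 1), "n_raters")
})

test_that("latent-factor loading controls within-factor correlations", {
  d <- build_design(config = list(items = c("a", "b", "c", "d"),
                                  factor_of = c("F", "F", "G", "G"),
                                  scale_min = 1, scale_max = 8,
                                  n_profiles = 1))
  # near-unit loading: same-factor positive items correlate > 0.9
  pop <- generate_population(d, within_factor_loading = 0.999,
                             loading_spread = 0, item_mean_sd = 0,
                             n_raters = 500, seed = 7)
  expect_gt(cor(pop$ratings[, "a"], pop$ratings[, "b"]), 0.9)
  # near-zero loading: correlations vanish in expectation
  pop0 <- generate_population(d, within_factor_loading = 0.02,
                              loading_spread = 0, n_raters = 500, seed = 7)
  s0 <- derive_similarity(pop0)
  expect_lt(max(abs(s0[upper.tri(s0)])), 0.15)
})

test_that("default structure separates within- from between-factor similarity", {
  d <- build_design("exp1")
  pop <- generate_population(d, n_raters = 300, seed = 21)
  s <- derive_similarity(pop)
  expect_equal(s, t(s), tolerance = 1e-12)
  expect_equal(unname(diag(s)), rep(1, 60))
  expect_true(all(abs(s) <= 1))
  same <- outer(d$factor_of, d$factor_of, "==")[upper.tri(s)]
  off <- s[upper.tri(s)]
  expect_gt(mean(abs(off[same])), mean(abs(off[!same])))
  # negative-valence items anti-correlate with positive ones of their factor
  f1 <- d$items[d$factor_of == d$factors[1]]
  pos <- f1[d$valence[f1] > 0]; neg <- f1[d$valence[f1] < 0]
  expect_lt(mean(s[pos, neg]), 0)
})

test_that("similarity is plain Pearson correlation with guarded degeneracies", {
  m <- cbind(x = c(1, 2, 3), y = c(1, 3, 2))
  expect_equal(derive_similarity(m)["x", "y"], 0.5)
  m2 <- cbind(a = c(1, 2, 4), b = c(1, 2, 4), c = -c(1, 2, 4))
  s <- derive_similarity(m2)
  expect_equal(s["a", "b"], 1)
  expect_equal(s["a", "c"], -1)
  expect_error(derive_similarity(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
  expect_error(derive_similarity(m[1, , drop = FALSE]), "2 raters")
})

test_that("reference points are per-item means that track the generator", {
  rp <- derive_reference_point(cbind(a = c(4, 6), b = c(7, 7)))
  expect_equal(unname(rp), c(5, 7), ignore_attr = TRUE)
  expect_identical(attr(rp, "source"), "population")
  # shifting the positive-item factor means shifts the reference point
  d <- build_design("exp2")  # all positive valence
  p1 <- generate_population(d, factor_means = 5, item_mean_sd = 0,
                            n_raters = 2000, seed = 3)
  p2 <- generate_population(d, factor_means = 6, item_mean_sd = 0,
                            n_raters = 2000, seed = 3)
  shift <- mean(derive_reference_point(p2) - derive_reference_point(p1))
  expect_equal(shift, 1, tolerance = 0.1)
})

test_that("constructed profiles follow the factor-mean plus noise recipe", {
  d <- build_design("exp2")
  p0 <- construct_profile(c(A = 5, C = 7), d, sd = 0)
  # zero noise: every item exactly at its factor mean
  expect_true(all(p0$feedback[d$factor_of == "A"] == 5))
  expect_true(all(p0$feedback[d$factor_of == "C"] == 7))
  expect_identical(p0$provenance, "constructed")

  p1 <- construct_profile(c(A = 7, C = 7), d, sd = 1, seed = 9)
  expect_true(all(p1$feedback %in% 1:8))
  # empirical factor mean within Monte-Carlo tolerance (SE ~ 1/sqrt(30),
  # inflated for rounding and capping)
  p2 <- construct_profile(c(A = 5, C = 7), d, sd = 1, seed = 10)
  expect_lt(abs(mean(p2$feedback[d$factor_of == "A"]) - 5), 0.4)

  expect_error(construct_profile(c(A = 5, Z = 7), d), "unknown factor")
})

test_that("stereotype reference points shift and jitter the population RP", {
  d <- build_design("exp1")
  rp <- setNames(runif(60, 3, 6), d$items)
  expect_equal(derive_stereotype_rp(rp, d, shift = 0, jitter_sd = 0),
               rp, ignore_attr = TRUE)
  sh <- derive_stereotype_rp(rp, d, shift = -0.9, jitter_sd = 0)
  expect_equal(mean(sh - rp), -0.9, tolerance = 1e-12)
  set.seed(1)
  st <- derive_stereotype_rp(rp, d, shift = -0.9, jitter_sd = 0.3, seed = 4)
  expect_identical(attr(st, "source"), "stereotype")
  expect_lt(t.test(st, rp, paired = TRUE)$p.value, 0.001)
})

test_that("divergent profile selection matches its advertised criteria", {
  d <- build_design("exp5")
  pop <- generate_population(d, n_raters = 400, seed = 31)
  prof <- select_divergent_profiles(pop, seed = 32)
  expect_length(prof, 5)
  mid <- (d$scale_min + d$scale_max) / 2
  oriented <- sweep(sweep(pop$ratings, 2, d$valence, `*`), 2,
                    (1 - d$valence) * mid, `+`)
  fs <- sapply(d$factors, function(f)
    rowMeans(oriented[, d$factor_of == f, drop = FALSE]))
  z <- scale(fs)
  for (k in seq_along(prof)) {
    expect_true(all(prof[[k]]$feedback %in% d$scale_min:d$scale_max))
    pk <- sweep(sweep(rbind(prof[[k]]$feedback), 2, d$valence, `*`), 2,
                (1 - d$valence) * mid, `+`)
    zk <- (sapply(d$factors, function(f)
      mean(pk[, d$factor_of == f])) - attr(z, "scaled:center")) /
      attr(z, "scaled:scale")
    expect_gt(abs(zk[k]), 1)
    expect_true(all(abs(zk[-k]) <= 1))
  }
})
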