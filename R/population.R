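#' Generate a synthetic rater population
#'
#' Draws a population of raters whose item ratings carry the block-correlation
#' structure assumed by the learning models: items within a personality
#' factor load on a shared latent factor, items across factors are
#' uncorrelated in expectation, and negative-valence items anti-correlate
#' with positive ones within their factor.
#'
#' The latent model for rater r on item i with factor f(i) is
#' \deqn{x_{ri} = m_i + s_i\,(\lambda_i\,g_{rf(i)} + \sqrt{1-\lambda_i^2}\,
#'   \epsilon_{ri})\,\sigma}
#' with standard-normal factor scores g and noise eps, item sign s_i (-1 for
#' negative-valence items), and item mean \eqn{m_i = mid + s_i\,(\mu_{f(i)} -
#' mid) + \delta_i} mirrored around the scale midpoint for negative items
#' and jittered per item. Ratings are rounded half-away-from-zero and capped
#' to the scale. Item loadings are drawn uniformly around the mean loading
#' (`loading_spread`), so pairwise within-factor correlations
#' \eqn{\lambda_i \lambda_j} are heterogeneous as in real trait ratings;
#' with equal loadings every within-factor pair would correlate identically
#' and fine-grained generalization would collapse onto the coarse factor
#' average.
#'
#' @param design a [build_design()] object.
#' @param within_factor_loading mean latent-factor loading lambda in (0, 1);
#'   the expected within-factor inter-item correlation is about lambda^2.
#' @param loading_spread half-width of the uniform per-item loading
#'   distribution around `within_factor_loading` (loadings are clamped to
#'   (0.01, 0.999)); 0 gives the exchangeable equal-loading structure.
#' @param factor_means base mean per factor for positive-valence items, on
#'   the rating scale; a single number is recycled. Default places positive
#'   items at 5/7 of the scale range above the minimum (6 on the 1-8 scale,
#'   so mirrored negative items sit near 3).
#' @param item_mean_sd spread of per-item mean endorsement around the factor
#'   base mean (scale units). Real trait words differ in how strongly an
#'   average person endorses them, which is what makes the per-item
#'   reference point informative; with a constant item mean the
#'   reference-point blend would be indistinguishable from a rescaled
#'   learning rate. Default 0.13 of the scale range (0.91 on the 1-8
#'   scale), calibrated so that after rounding and capping the realized
#'   per-item spread of the reference point within a valence class is about
#'   0.69 scale units, a realistic spread for student trait averages on
#'   the 8-point scale.
#' @param rating_sd total latent standard deviation sigma in scale units.
#' @param n_raters number of raters (>= 2).
#' @param seed optional integer seed.
#' @return object of class `tl_population`: list with `ratings` (rater x item
#'   integer matrix, item ids as column names) and `design`.
#' @examples
#' d <- build_design("exp1")
#' pop <- generate_population(d, n_raters = 100, seed = 1)
#' range(pop$ratings)
#' @export
generate_population <- function(design, within_factor_loading = 0.6,
                                loading_spread = 0.3, factor_means = NULL,
                                item_mean_sd = NULL, rating_sd = 1.5,
                                n_raters = 300, seed = NULL) {
  stopifnot(inherits(design, "tl_design"))
  lam <- within_factor_loading
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0 || lam >= 1)
    stop("within_factor_loading must be a single number in (0, 1)")
  if (!is.numeric(n_raters) || n_raters < 2)
    stop("n_raters must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  nf <- length(design$factors)
  ni <- length(design$items)
  if (is.null(factor_means))
    factor_means <- design$scale_min + (5 / 7) * (design$scale_max - design$scale_min)
  factor_means <- rep_len(factor_means, nf)
  names(factor_means) <- design$factors
  if (is.null(item_mean_sd))
    item_mean_sd <- 0.13 * (design$scale_max - design$scale_min)
  mid <- (design$scale_min + design$scale_max) / 2
  s <- design$valence
  item_mean <- mid + s * (factor_means[design$factor_of] - mid) +
    rnorm(ni, 0, item_mean_sd)
  fac_idx <- match(design$factor_of, design$factors)
  lam_i <- pmin(0.999, pmax(0.01,
    runif(ni, lam - loading_spread, lam + loading_spread)))
  g <- matrix(rnorm(n_raters * nf), n_raters, nf)
  eps <- matrix(rnorm(n_raters * ni), n_raters, ni)
  latent <- sweep(g[, fac_idx, drop = FALSE], 2, lam_i, `*`) +
    sweep(eps, 2, sqrt(1 - lam_i^2), `*`)
  raw <- sweep(latent * rating_sd, 2, s, `*`)
  raw <- sweep(raw, 2, item_mean, `+`)
  ratings <- round_cap(raw, design)
  dimnames(ratings) <- list(NULL, design$items)
  structure(list(ratings = ratings, design = design),
            class = "tl_population")
}

#' @export
print.tl_population <- function(x, ...) {
  cat("Synthetic rater population:", nrow(x$ratings), "raters x",
      ncol(x$ratings), "items on [", x$design$scale_min, ",",
      x$design$scale_max, "]\n")
  invisible(x)
}

#' Item-by-item similarity matrix from a rater population
#'
#' Pairwise Pearson correlations of item ratings across raters, the signed
#' similarity structure that fine-granularity models use to generalize
#' prediction errors across traits. The diagonal is forced to exactly 1.
#'
#' @param pop a [generate_population()] object, or a rater x item rating
#'   matrix with item ids as column names.
#' @return symmetric item x item correlation matrix with unit diagonal.
#' @examples
#' pop <- generate_population(build_design("exp2"), n_raters = 200, seed = 2)
#' sim <- derive_similarity(pop)
#' all(diag(sim) == 1)
#' @export
derive_similarity <- function(pop) {
  ratings <- if (inherits(pop, "tl_population")) pop$ratings else as.matrix(pop)
  if (nrow(ratings) < 2) stop("at least 2 raters are needed")
  sds <- apply(ratings, 2, sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(colnames(ratings)[sds == 0], collapse = ", "),
         " (degenerate population)")
  sim <- cor(ratings)
  diag(sim) <- 1
  sim
}

#' Reference point from a rater population
#'
#' The per-item mean rating of a comparison group, used by the
#' reference-point models as an a-priori expectation about an average
#' person.
#'
#' @inheritParams derive_similarity
#' @return named numeric vector of per-item means with attribute
#'   `source = "population"`.
#' @export
derive_reference_point <- function(pop) {
  ratings <- if (inherits(pop, "tl_population")) pop$ratings else as.matrix(pop)
  if (nrow(ratings) < 1) stop("population is empty")
  rp <- colMeans(ratings)
  attr(rp, "source") <- "population"
  rp
}

#' Sample feedback profiles from a population
#'
#' Draws rater rows from a population to serve as "real" profiles: the
#' to-be-learned self-ratings of target persons.
#'
#' @param pop a [generate_population()] object.
#' @param n number of profiles; defaults to the design's `n_profiles`.
#' @param seed optional integer seed.
#' @return list of `tl_profile` objects (named integer feedback vector plus
#'   `provenance = "sampled"`).
#' @export
sample_profiles <- function(pop, n = NULL, seed = NULL) {
  stopifnot(inherits(pop, "tl_population"))
  if (!is.null(seed)) set.seed(seed)
  n <- n %||% pop$design$n_profiles
  rows <- sample.int(nrow(pop$ratings), n)
  lapply(rows, function(r) {
    structure(list(feedback = pop$ratings[r, ], provenance = "sampled"),
              class = "tl_profile")
  })
}

#' Select divergent profiles from a population
#'
#' Reproduces the IPIP-style profile selection: each of the returned
#' profiles is a rater whose mean rating on one target factor deviates by
#' more than `z_div` population SDs from the factor's population mean while
#' staying within `z_avg` SDs on every other factor -- so each profile is divergent
#' on a different factor and average otherwise. Factor scores are computed
#' on valence-oriented ratings (negative items mirrored around the scale
#' midpoint) so that "high on the factor" is well defined for mixed-valence
#' item sets.
#'
#' @param pop a [generate_population()] object.
#' @param z_div divergence threshold in population SDs (default 1).
#' @param z_avg allowed deviation on the non-target factors (default 1).
#' @param seed optional integer seed.
#' @return list of `tl_profile`s (one per design factor, in design factor
#'   order) with `provenance = "sampled"`.
#' @export
select_divergent_profiles <- function(pop, z_div = 1, z_avg = 1,
                                      seed = NULL) {
  stopifnot(inherits(pop, "tl_population"))
  if (!is.null(seed)) set.seed(seed)
  design <- pop$design
  mid <- (design$scale_min + design$scale_max) / 2
  oriented <- sweep(sweep(pop$ratings, 2, design$valence, `*`), 2,
                    (1 - design$valence) * mid, `+`)
  fac_score <- sapply(design$factors, function(f)
    rowMeans(oriented[, design$factor_of == f, drop = FALSE]))
  z <- scale(fac_score)
  used <- integer(0)
  lapply(seq_along(design$factors), function(k) {
    ok <- which(abs(z[, k]) > z_div &
                apply(abs(z[, -k, drop = FALSE]) <= z_avg, 1, all))
    ok <- setdiff(ok, used)
    if (!length(ok))
      stop("no rater divergent on factor ", design$factors[k],
           "; enlarge the population")
    r <- if (length(ok) == 1) ok else sample(ok, 1)
    used <<- c(used, r)
    structure(list(feedback = pop$ratings[r, ], provenance = "sampled"),
              class = "tl_profile")
  })
}

#' Construct an artificial feedback profile
#'
#' Builds a profile by fixing a mean per factor, adding per-item Gaussian
#' noise (default SD 1), rounding to the nearest integer and capping to the
#' rating scale. This is the constructed-profile procedure that removes the
#' fine-grained trait similarity structure while preserving factor-level
#' structure.
#'
#' @param factor_means named numeric vector, one mean per design factor,
#'   each within the scale bounds.
#' @param design a [build_design()] object.
#' @param sd per-item noise standard deviation (scale units).
#' @param seed optional integer seed.
#' @return a `tl_profile` with `provenance = "constructed"`.
#' @examples
#' d <- build_design("exp2")
#' p <- construct_profile(c(A = 5, C = 7), d, sd = 1, seed = 3)
#' tapply(p$feedback, d$factor_of, mean)
#' @export
construct_profile <- function(factor_means, design, sd = 1, seed = NULL) {
  stopifnot(inherits(design, "tl_design"))
  if (is.null(names(factor_means)))
    names(factor_means) <- design$factors[seq_along(factor_means)]
  unknown <- setdiff(names(factor_means), design$factors)
  if (length(unknown))
    stop("mean given for unknown factor(s): ", paste(unknown, collapse = ", "))
  if (length(factor_means) != length(design$factors))
    stop("one mean per factor is required")
  if (any(factor_means < design$scale_min | factor_means > design$scale_max))
    stop("factor means must lie within the scale bounds")
  if (!is.null(seed)) set.seed(seed)
  mu <- factor_means[design$factor_of]
  fb <- round_cap(mu + rnorm(length(mu), 0, sd), design)
  names(fb) <- design$items
  structure(list(feedback = fb, provenance = "constructed"),
            class = "tl_profile")
}

#' @export
print.tl_profile <- function(x, ...) {
  cat("Feedback profile (", x$provenance, "), ", length(x$feedback),
      " items, mean ", round(mean(x$feedback), 2), "\n", sep = "")
  invisible(x)
}

#' Derive a stereotype reference point
#'
#' Produces a shifted, jittered copy of a population reference point as a
#' surrogate for pre-task stereotype ratings of an out-group (e.g., the
#' systematically lower impressions participants hold of an average fashion
#' model). Values are capped to the rating scale.
#'
#' @param rp named per-item reference point (see
#'   [derive_reference_point()]).
#' @param design the experiment design (for the scale bounds).
#' @param shift systematic shift in scale units (default -0.9, matching the
#'   observed gap between in-group and out-group averages).
#' @param jitter_sd per-item Gaussian jitter SD.
#' @param seed optional integer seed.
#' @return named numeric vector with attribute `source = "stereotype"`.
#' @export
derive_stereotype_rp <- function(rp, design, shift = -0.9, jitter_sd = 0.3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- cap_scale(rp + shift + rnorm(length(rp), 0, jitter_sd), design)
  names(out) <- names(rp)
  attr(out, "source") <- "stereotype"
  out
}

#' Write / read a rater x item rating matrix as TSV
#'
#' @param ratings rater x item matrix (or `tl_population`).
#' @param path file path.
#' @return `read_ratings` returns the matrix with item-id column names.
#' @export
write_ratings <- function(ratings, path) {
  if (inherits(ratings, "tl_population")) ratings <- ratings$ratings
  write.table(ratings, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Write / read a square labelled similarity matrix as TSV
#'
#' @param sim item x item similarity matrix with item-id dimnames.
#' @param path file path.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(item = rownames(sim), sim, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m)))
    stop("similarity matrix must be square with matching row/column labels")
  m
}
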