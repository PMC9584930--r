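#' Build a complete synthetic study surrogate for an experiment preset
#'
#' One-stop constructor for simulation studies: builds the preset design,
#' generates a rater population with the default structure, derives the
#' similarity matrix and population reference point from it, and assembles
#' the feedback profiles the way the corresponding experiment did:
#' \describe{
#'   \item{exp1, exp3, exp4}{profiles are rater rows sampled from the
#'     population; exp4 additionally carries a stereotype reference point
#'     (`rp_stereotype`, shifted about -0.9 with jitter).}
#'   \item{exp2}{four constructed profiles with the factor-mean combinations
#'     (5, 5), (5, 7), (7, 5), (7, 7), per-item noise SD 1, rounded and
#'     capped to 1-8.}
#'   \item{exp5}{five profiles selected to be divergent (beyond 1 population
#'     SD) on one distinct factor each and average on the rest.}
#' }
#'
#' @param preset `"exp1"` ... `"exp5"`.
#' @param seed integer seed governing population, profiles and any jitter
#'   (sub-seeds are derived deterministically).
#' @param n_raters population size passed to [generate_population()].
#' @param ... further arguments to [generate_population()].
#' @return list with `design`, `population`, `sim`, `rp`, `profiles`, and
#'   for exp4 also `rp_stereotype`.
#' @examples
#' s <- build_surrogate("exp2", seed = 1, n_raters = 100)
#' sapply(s$profiles, function(p) mean(p$feedback))
#' @export
build_surrogate <- function(preset, seed = 1, n_raters = 300, ...) {
  design <- build_design(preset)
  pop <- generate_population(design, n_raters = n_raters, seed = seed, ...)
  sim <- derive_similarity(pop)
  rp <- derive_reference_point(pop)
  profiles <- switch(preset,
    exp2 = {
      combos <- list(c(5, 5), c(5, 7), c(7, 5), c(7, 7))
      lapply(seq_along(combos), function(i)
        construct_profile(setNames(combos[[i]], design$factors), design,
                          sd = 1, seed = seed + 1000L + i))
    },
    exp5 = select_divergent_profiles(pop, seed = seed + 2000L),
    sample_profiles(pop, design$n_profiles, seed = seed + 3000L))
  out <- list(design = design, population = pop, sim = sim, rp = rp,
              profiles = profiles)
  if (preset == "exp4")
    out$rp_stereotype <- derive_stereotype_rp(rp, design,
                                              seed = seed + 4000L)
  out
}
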