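# Monte-Carlo validation of the support-interval procedure.

#' Coverage of the 1.5-LOD support interval
#'
#' Simulates replicate single-QTL intercross (F2) datasets, scans each
#' with Haley-Knott regression on a regular marker grid, computes the
#' support interval with the closest-marker-outside rule, and reports the
#' percentage of replicates whose interval contains the true QTL
#' position.  With `drop = 1.5` this rate is expected to sit near 95%,
#' the conventional confidence level attributed to the 1.5-LOD interval
#' in intercrosses.
#'
#' @param n_reps Number of replicate datasets.
#' @param n Individuals per replicate.
#' @param spacing_cm Marker spacing in cM.
#' @param length_cm Scanned region length in cM.
#' @param qtl_cm True QTL position in cM.
#' @param h2 Fraction of phenotypic variance explained by the additive
#'   QTL (residual SD 1).
#' @param drop Support-interval LOD drop.
#' @param seeds Integer vector of per-replicate seeds (length `n_reps`).
#' @return Coverage percentage, with attribute `covered` (logical per
#'   replicate).
#' @export
interval_coverage <- function(n_reps = 300, n = 400, spacing_cm = 5,
                              length_cm = 100, qtl_cm = 52, h2 = 0.10,
                              drop = 1.5, seeds = seq_len(n_reps)) {
  stopifnot(length(seeds) == n_reps, h2 > 0, h2 < 1)
  pos <- seq(0, length_cm, by = spacing_cm)
  map <- genetic_map(sprintf("M%02d", seq_along(pos)), "1", pos)
  a <- sqrt(2 * h2 / (1 - h2))
  qtl <- qtl_spec(qtl_cm, "additive",
                  effect_AA = -a, effect_AB = 0, effect_BB = a)
  n_couples <- max(2, floor(n / 16))
  n_off <- ceiling(n / n_couples)
  covered <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(map, list(qtl), n_generations = 2,
                      n_couples = n_couples, n_offspring = n_off,
                      family_effect_sd = 0, residual_sd = 1,
                      trait_mean = 0, base_penetrance = 0.5,
                      cm_per_mb = 1, seed = seeds[i])
    sim <- simulate_ail(cfg)
    keep <- seq_len(min(n, nrow(sim$phenotypes)))
    g <- genotype_matrix(unclass(sim$genotypes)[keep, , drop = FALSE], map)
    probs <- conditional_probabilities(g, sim$map, expansion = 1)
    sc <- scan_hk(sim$phenotypes$SEV[keep], probs, trait_name = "SEV")
    si <- support_interval(sc, drop = drop)
    si$lower <= qtl_cm && qtl_cm <= si$upper
  }, NA)
  structure(100 * mean(covered), covered = covered)
}
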