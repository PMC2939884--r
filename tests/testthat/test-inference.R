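make_scan <- function(pos, lod) {
  scan_result(pos, lod, trait = "t", model = "haley_knott", n = 100L)
}

test_that("support intervals follow the closest-marker-outside rule", {
  si <- support_interval(make_scan(c(10, 20, 30, 40, 50), c(1, 2, 5, 2, 1)))
  expect_equal(si$peak_pos, 30)
  expect_equal(c(si$lower, si$upper), c(20, 40))

  # monotone rising curve: upper bound clipped at the region end
  si <- support_interval(make_scan(c(10, 20, 30), c(0, 2, 4)))
  expect_equal(si$peak_pos, 30)
  expect_equal(si$upper, 30)
  expect_equal(si$lower, 20)

  # flat curve: no marker ever drops 1.5, interval = whole region
  si <- support_interval(make_scan(c(10, 20, 30), c(2, 2, 2)))
  expect_equal(si$peak_pos, 10)  # tie broken toward smallest position
  expect_equal(c(si$lower, si$upper), c(10, 30))
})

test_that("widening the drop never narrows the interval and always contains the peak", {
  set.seed(5)
  for (i in 1:25) {
    sc <- make_scan(sort(runif(15, 0, 100)), runif(15, 0, 6))
    prev <- NULL
    for (drop in c(0.5, 1.5, 3)) {
      si <- support_interval(sc, drop)
      expect_lte(si$lower, si$peak_pos)
      expect_gte(si$upper, si$peak_pos)
      if (!is.null(prev)) {
        expect_lte(si$lower, prev$lower)
        expect_gte(si$upper, prev$upper)
      }
      prev <- si
    }
  }
})

test_that("fallback threshold is the fixed 3.4 cut-off", {
  thr <- fallback_threshold()
  expect_equal(thr$threshold, 3.4)
  expect_equal(thr$method, "fixed_3.4")
})

test_that("family-residual threshold rejects degenerate family structure", {
  fx <- make_eae23_fixture(seed = 41, n_offspring = 6)
  ph <- fx$phenotypes
  probs <- conditional_probabilities(fx$genotypes, fx$map, expansion = 5)
  expect_error(
    family_residual_threshold(ph$MAX, probs, rep("f1", nrow(ph))),
    ">= 2 families")
  # trait equal to its family mean: residuals all zero
  fam_mean <- stats::ave(ph$MAX, ph$family)
  expect_error(
    family_residual_threshold(fam_mean, probs, ph$family),
    "zero variance")
})

test_that("family-residual threshold sits inside the within-family permutation band", {
  # family effects but no QTL
  map <- genetic_map(sprintf("M%d", 1:8), "1", seq(0, 70, by = 10))
  cfg <- sim_config(map, qtl_specs = list(), n_generations = 10,
                    n_couples = 30, n_offspring = 8,
                    family_effect_sd = 0.6, residual_sd = 1,
                    base_penetrance = 0.3, seed = 51)
  sim <- simulate_ail(cfg)
  ph <- sim$phenotypes
  probs <- conditional_probabilities(sim$genotypes, sim$map, expansion = 5)
  thr <- family_residual_threshold(ph$SEV, probs, ph$family)

  set.seed(52)
  null_max <- vapply(1:500, function(i) {
    yp <- unsplit(lapply(split(ph$SEV, ph$family), sample), ph$family)
    res <- yp - stats::ave(yp, ph$family)
    max(scan_hk(res, probs)$lod)
  }, 0)
  band <- stats::quantile(null_max, c(0.025, 0.975))
  expect_gte(thr$threshold, band[[1]])
  expect_lte(thr$threshold, band[[2]])
})

test_that("two-QTL fit separates a real locus from an empty one", {
  map <- genetic_map(sprintf("M%d", 1:5), "1", c(0, 20, 40, 60, 80))
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(map, list(qtl_spec(20, "additive", effect_AA = -0.6,
                                         effect_BB = 0.6)),
                      n_generations = 2, n_couples = 10, n_offspring = 15,
                      residual_sd = 1, base_penetrance = 0.5, seed = s)
    sim <- simulate_ail(cfg)
    probs <- conditional_probabilities(sim$genotypes, sim$map)
    fit <- fit_two_qtl(sim$phenotypes$SEV, probs, 20, 60)
    c(fit$p_value[1] < 0.01, fit$p_value[2] >= 0.05)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)  # locus A detected at 0.01
  expect_gte(mean(hits[2, ]), 0.9)  # locus B quiet at 0.05
})

test_that("two-QTL fit validates its inputs", {
  fx <- random_fixture(61, n_offspring = 8)
  probs <- conditional_probabilities(fx$genotypes, fx$map)
  y <- fx$phenotypes$SEV
  expect_error(fit_two_qtl(y, probs, 20, 20), "must differ")

  # collinear loci: two markers at 0 cM
  map <- genetic_map(c("M1", "M2"), "1", c(10, 10.001))
  map$pos_cm <- c(5, 5)
  cfg <- sim_config(map, n_generations = 2, n_couples = 10,
                    n_offspring = 10, seed = 62)
  sim <- simulate_ail(cfg)
  p2 <- conditional_probabilities(sim$genotypes, sim$map)
  expect_error(fit_two_qtl(sim$phenotypes$SEV, p2, 10, 10.001), "collinear")
})

test_that("bootstrap localization is reproducible, bounded and well-behaved", {
  fx <- make_eae23_fixture(seed = 71)
  f <- fx$phenotypes$sex == "F"
  ph <- fx$phenotypes[f, ]
  probs <- conditional_probabilities(
    genotype_matrix(unclass(fx$genotypes)[f, , drop = FALSE], fx$map),
    fx$map, expansion = 5)
  sc <- scan_hk(ph$MAX, probs)
  peaks <- find_qtl_peaks(sc, threshold = 2, max_peaks = 2)
  expect_length(peaks, 2)

  p1 <- localization_probability(ph$MAX, probs, peaks, threshold = 2,
                                 n_boot = 60, seed = 7)
  p2 <- localization_probability(ph$MAX, probs, peaks, threshold = 2,
                                 n_boot = 60, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 100))
  expect_lte(sum(p1), 100)
  # both linked QTLs receive support
  expect_true(all(p1 > 0))

  # an overwhelming QTL with a whole-region interval is always localized
  whole <- list(structure(list(peak_pos = 47.3, peak_lod = max(sc$lod),
                               lower = min(sc$pos_mb), upper = max(sc$pos_mb),
                               drop = 1.5), class = "support_interval"))
  p_all <- localization_probability(ph$MAX, probs, whole, threshold = 0.5,
                                    n_boot = 40, seed = 8)
  expect_gte(p_all[1], 95)

  # pure noise almost never clears the 3.4 cut-off
  set.seed(9)
  noise <- rnorm(nrow(ph))
  small <- list(structure(list(peak_pos = 47.3, peak_lod = 1,
                               lower = 45, upper = 50.5, drop = 1.5),
                          class = "support_interval"))
  p_noise <- localization_probability(noise, probs, small, threshold = 3.4,
                                      n_boot = 40, seed = 10)
  expect_lte(p_noise[1], 5)

  expect_error(localization_probability(ph$MAX, probs, peaks, 2, n_boot = 0),
               "n_boot")
  expect_warning(
    localization_probability(ph$MAX, probs,
                             list(peaks[[1]], peaks[[1]]), 2,
                             n_boot = 5, seed = 1),
    "overlap")
})

test_that("sub-threshold replicates can be excluded from the denominator", {
  fx <- make_eae23_fixture(seed = 81, n_offspring = 6)
  ph <- fx$phenotypes
  probs <- conditional_probabilities(fx$genotypes, fx$map, expansion = 5)
  sc <- scan_hk(ph$MAX, probs)
  peaks <- find_qtl_peaks(sc, threshold = 1.5, max_peaks = 2)
  pin <- localization_probability(ph$MAX, probs, peaks, threshold = 2.5,
                                  n_boot = 50, seed = 3,
                                  count_subthreshold = TRUE)
  pout <- localization_probability(ph$MAX, probs, peaks, threshold = 2.5,
                                   n_boot = 50, seed = 3,
                                   count_subthreshold = FALSE)
  expect_true(all(pout >= pin - 1e-9))
})
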