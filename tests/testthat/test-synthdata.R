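test_that("zero genetic distance forbids recombination", {
  map <- genetic_map(c("M1", "M2"), "1", c(10, 10.001))
  map$pos_cm <- c(5, 5)  # 0 cM apart
  cfg <- sim_config(map, n_generations = 4, n_couples = 10,
                    n_offspring = 20, seed = 3)
  sim <- simulate_ail(cfg)
  g <- unclass(sim$genotypes)
  expect_true(all(g[, 1] == g[, 2]))
})

test_that("F2 genotype frequencies are 1:2:1 at an effectively unlinked marker", {
  map <- genetic_map(c("M1", "M2"), "1", c(0, 600))  # ~unlinked, r ~ 0.5
  cfg <- sim_config(map, n_generations = 2, n_couples = 10,
                    n_offspring = 200, seed = 42)
  sim <- simulate_ail(cfg)
  for (j in 1:2) {
    counts <- table(factor(unclass(sim$genotypes)[, j],
                           levels = c("AA", "AB", "BB")))
    n <- sum(counts)
    # exact binomial test per class against 1:2:1 at alpha = 0.001
    expect_gt(stats::binom.test(counts[["AA"]], n, 0.25)$p.value, 0.001)
    expect_gt(stats::binom.test(counts[["AB"]], n, 0.50)$p.value, 0.001)
    expect_gt(stats::binom.test(counts[["BB"]], n, 0.25)$p.value, 0.001)
  }
})

test_that("recombinant fraction between linked markers expands from F2 to G10", {
  map <- genetic_map(c("M1", "M2"), "1", c(0, 10))  # 10 cM apart
  frac_discordant <- function(n_gen, seed) {
    cfg <- sim_config(map, n_generations = n_gen, n_couples = 12,
                      n_offspring = 16, seed = seed)
    g <- unclass(simulate_ail(cfg)$genotypes)
    mean(g[, 1] != g[, 2])
  }
  f2 <- vapply(1:50, function(s) frac_discordant(2, s), 0)
  g10 <- vapply(1:50, function(s) frac_discordant(10, 1000 + s), 0)
  expect_gt(mean(g10), mean(f2))
})

test_that("meiosis respects Mendelian transmission and the Haldane map", {
  set.seed(9)
  # every gamete allele must come from one of the parent's two haplotypes
  h1 <- matrix(rbinom(200 * 5, 1, 0.5), 200, 5)
  h2 <- matrix(rbinom(200 * 5, 1, 0.5), 200, 5)
  r <- rep(0.2, 4)
  gam <- ailqtl:::make_gametes(h1, h2, r)
  expect_true(all(gam == h1 | gam == h2))

  # single-meiosis recombinant fraction over 10^4 F1 meioses within 3 SE
  # of the Haldane prediction
  d <- 20
  r_true <- 0.5 * (1 - exp(-2 * d / 100))
  n <- 10000
  gam <- ailqtl:::make_gametes(matrix(0L, n, 2), matrix(1L, n, 2),
                               haldane(d))
  r_hat <- mean(gam[, 1] != gam[, 2])
  se <- sqrt(r_true * (1 - r_true) / n)
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("identical config and seed give identical outputs", {
  fx1 <- make_eae23_fixture(seed = 5, n_offspring = 4)
  fx2 <- make_eae23_fixture(seed = 5, n_offspring = 4)
  expect_identical(fx1$genotypes, fx2$genotypes)
  expect_identical(fx1$phenotypes, fx2$phenotypes)
  expect_identical(fx1$pedigree, fx2$pedigree)
  td <- withr::local_tempdir()
  write_phenotypes(fx1$phenotypes, file.path(td, "a.csv"))
  write_phenotypes(fx2$phenotypes, file.path(td, "b.csv"))
  expect_identical(readLines(file.path(td, "a.csv")),
                   readLines(file.path(td, "b.csv")))
})

test_that("genetic drift strengthens as breeding couples decrease", {
  map <- genetic_map(c("M1", "M2"), "1", c(0, 400))
  fixed_frac <- function(n_couples, seed) {
    cfg <- sim_config(map, n_generations = 10, n_couples = n_couples,
                      n_offspring = 4, seed = seed)
    g <- unclass(simulate_ail(cfg)$genotypes)
    mean(apply(g, 2, function(col) all(col == "AA") || all(col == "BB")))
  }
  reps <- 150
  f10 <- mean(vapply(seq_len(reps), function(s) fixed_frac(10, s), 0))
  f25 <- mean(vapply(seq_len(reps), function(s) fixed_frac(25, 10000 + s), 0))
  f50 <- mean(vapply(seq_len(reps), function(s) fixed_frac(50, 20000 + s), 0))
  expect_gt(f10, 0)
  expect_gte(f10, f25)
  expect_gte(f25, f50)
})

test_that("the default cohort matches its design: 20 markers over 13.9-81.6 Mb, ~29% incidence", {
  map <- eae23_map()
  expect_equal(nrow(map), 20)
  expect_equal(map$pos_mb[1], 13.9)
  expect_equal(map$pos_mb[20], 81.6)
  expect_equal(map_span(map), 67.7)

  inc <- vapply(1:30, function(s) {
    mean(make_eae23_fixture(seed = s)$phenotypes$INC)
  }, 0)
  expect_lt(abs(mean(inc) - 0.29), 0.05)
})

test_that("simulation config rejects invalid architectures", {
  map <- eae23_map()
  expect_error(sim_config(map, n_generations = 1), "n_generations")
  expect_error(sim_config(map, n_couples = 0), "n_couples")
  expect_error(sim_config(map, residual_sd = 0), "residual_sd")
  expect_error(qtl_spec(50, "additive", effect_AA = Inf), "finite")
  expect_error(qtl_spec(50, "heterosis", effect_AA = 0, effect_AB = 0.5,
                        effect_BB = 1), "outside")
  expect_error(qtl_spec(50, "additive", pen_AA = 1.2, pen_AB = 0.5,
                        pen_BB = 0.5), "0, 1")
  expect_error(sim_config(map, list(qtl_spec(99, "additive"))), "span")
})
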