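# Independent brute-force oracles used to validate the package's
# computations on small instances.  These deliberately avoid the code
# paths they check.

# Closed-form least-squares LOD at a fully typed marker via the normal
# equations, with intercross coding a = -1/0/1, d = 1{AB}.
oracle_hk_lod <- function(y, gclass, covar = NULL) {
  a <- c(AA = -1, AB = 0, BB = 1)[gclass]
  d <- as.numeric(gclass == "AB")
  rss <- function(X) {
    # pseudoinverse handles markers with an absent genotype class
    b <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
    sum((y - X %*% b)^2)
  }
  X0 <- cbind(rep(1, length(y)), covar)
  X1 <- cbind(X0, a, d)
  (length(y) / 2) * log10(rss(X0) / rss(X1))
}

# Saturated three-class binomial MLE LOD for a binary trait at a fully
# typed marker (intercept + a + d saturates the three classes).
oracle_binary_lod <- function(y, gclass) {
  ll_counts <- function(k, n) {
    p <- k / n
    term <- function(kk, pp) if (kk == 0) 0 else kk * log(pp)
    sum(mapply(function(kk, nn, pp) term(kk, pp) + term(nn - kk, 1 - pp),
               k, n, p))
  }
  k <- tapply(y, gclass, sum)
  n <- tapply(y, gclass, length)
  l1 <- ll_counts(as.numeric(k), as.numeric(n))
  l0 <- ll_counts(sum(y), length(y))
  (l1 - l0) / log(10)
}

# Exact two-sided Mann-Whitney p by full enumeration of group
# assignments (untied data, small n).
oracle_mw_exact <- function(x1, x2) {
  comb <- c(x1, x2)
  n1 <- length(x1)
  u_of <- function(idx) {
    g1 <- comb[idx]; g2 <- comb[-idx]
    sum(outer(g1, g2, ">"))
  }
  splits <- utils::combn(length(comb), n1)
  us <- apply(splits, 2, u_of)
  u_obs <- sum(outer(x1, x2, ">"))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Fisher's exact two-sided p by hypergeometric enumeration.
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

# Genotype-class probabilities at locus `target` by enumeration of all
# ordered haplotype pairs along the whole chain (Haldane, expansion on
# the cM scale).  `obs` is a vector of "AA"/"AB"/"BB"/NA.
oracle_enum_genoprob <- function(obs, pos_cm, target, expansion = 1) {
  L <- length(pos_cm)
  r <- 0.5 * (1 - exp(-2 * diff(pos_cm) * expansion / 100))
  haps <- as.matrix(expand.grid(rep(list(0:1), L)))
  hp <- apply(haps, 1, function(h) {
    p <- 0.5
    for (j in seq_len(L - 1)) {
      p <- p * (if (h[j] == h[j + 1]) 1 - r[j] else r[j])
    }
    p
  })
  codes <- c("AA", "AB", "BB")
  out <- c(AA = 0, AB = 0, BB = 0)
  for (i in seq_len(nrow(haps))) {
    for (j in seq_len(nrow(haps))) {
      g <- codes[haps[i, ] + haps[j, ] + 1]
      if (any(!is.na(obs) & g != obs)) next
      out[g[target]] <- out[g[target]] + hp[i] * hp[j]
    }
  }
  out / sum(out)
}

# Small random cohort for round-trip and property tests.
random_fixture <- function(seed, n_markers = 6, n_offspring = 4) {
  pos <- sort(stats::runif(n_markers, 0, 80))
  pos <- pos + seq_along(pos) * 1e-3  # enforce strict increase
  map <- genetic_map(sprintf("M%02d", seq_len(n_markers)), "1", pos)
  cfg <- sim_config(map, list(qtl_spec(mean(pos), "additive",
                                       effect_AA = -0.5, effect_BB = 0.5)),
                    n_generations = 3, n_couples = 12,
                    n_offspring = n_offspring, base_penetrance = 0.4,
                    geno_missing = 0.05, seed = seed)
  simulate_ail(cfg)
}

# Fully typed single-generation genotype matrix + probability grid at
# the markers (used where the map plays no role beyond marker identity).
typed_grid <- function(gclass_matrix, pos_mb = NULL) {
  n <- nrow(gclass_matrix)
  m <- ncol(gclass_matrix)
  if (is.null(pos_mb)) pos_mb <- seq(10, by = 10, length.out = m)
  map <- genetic_map(sprintf("M%02d", seq_len(m)), "1", pos_mb)
  rownames(gclass_matrix) <- sprintf("id%03d", seq_len(n))
  colnames(gclass_matrix) <- map$marker
  geno <- genotype_matrix(gclass_matrix, map)
  conditional_probabilities(geno, map)
}
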