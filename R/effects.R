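# Allelic-effect stratification at peak markers, nonparametric testing
# with Bonferroni control, heterosis/transgression classification, and
# genotype-matched congenic phenotype prediction.

#' Bonferroni adjustment
#'
#' @param p P-value(s).
#' @param m_tests Number of tests in the family.
#' @return `min(1, p * m_tests)`, element-wise; never smaller than `p`.
#' @export
bonferroni_adjust <- function(p, m_tests = 1) {
  stopifnot(m_tests >= 1)
  pmin(1, p * m_tests)
}

#' Nonparametric group comparisons
#'
#' Wraps the rank tests the pipeline uses on heavily tied clinical-score
#' data: Kruskal-Wallis across all groups, Mann-Whitney U for two groups
#' (exact enumeration for small untied samples, tie-corrected normal
#' approximation otherwise), and Fisher's exact test when a 2x2 count
#' table is supplied.  All tests are two-sided.
#'
#' @param groups List of numeric vectors (one per group), or `NULL` when
#'   only `counts` is used.
#' @param counts Optional 2x2 matrix of counts for Fisher's exact test.
#' @return Named list with whichever of `kruskal_wallis`, `mann_whitney`,
#'   `fisher_exact` apply.
#' @export
nonparametric_tests <- function(groups = NULL, counts = NULL) {
  out <- list()
  if (!is.null(groups)) {
    if (length(groups) < 2) stop("need >= 2 groups")
    if (any(vapply(groups, length, 0L) == 0)) stop("empty group")
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
    if (length(unique(x)) > 1) {
      out$kruskal_wallis <- stats::kruskal.test(x, g)$p.value
    } else {
      out$kruskal_wallis <- 1
    }
    if (length(groups) == 2) {
      if (length(unique(x)) == 1) {
        out$mann_whitney <- 1
      } else {
        exact <- length(x) <= 12 && !any(duplicated(x))
        out$mann_whitney <- suppressWarnings(
          stats::wilcox.test(groups[[1]], groups[[2]], exact = exact,
                             correct = !exact)$p.value)
      }
    }
  }
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == c(2, 2))) stop("Fisher's test needs a 2x2 table")
    out$fisher_exact <- stats::fisher.test(counts)$p.value
  }
  out
}

# Fisher p for incidence in two genotype classes.
fisher_inc <- function(inc1, inc2) {
  tab <- rbind(c(sum(inc1 == 1), sum(inc1 == 0)),
               c(sum(inc2 == 1), sum(inc2 == 0)))
  stats::fisher.test(tab)$p.value
}

#' Allelic-effect stratification and classification at a marker
#'
#' Splits the cohort by genotype class at a peak marker, summarizes each
#' class, tests the marker's influence (Kruskal-Wallis per quantitative
#' trait, pairwise Mann-Whitney contrasts, Fisher's exact for incidence)
#' with Bonferroni adjustment, and classifies the allelic architecture
#' from the contrast pattern.  Contrast significance pools evidence
#' across the clinical panel (minimum adjusted p per contrast) with each
#' trait oriented so larger means more severe (day of onset flipped):
#' \itemize{
#'   \item `heterosis` -- the heterozygote differs from both homozygotes
#'     in the same direction;
#'   \item `dominant_A` / `dominant_B` -- the heterozygote tracks the
#'     named allele's homozygote while the homozygotes differ;
#'   \item `additive` -- homozygotes differ with the heterozygote
#'     intermediate;
#'   \item `none` -- no significant contrast.
#' }
#' The transgressive flag is set when the resistant-strain allele's
#' homozygote class has the higher incidence (more severe phenotype)
#' and the homozygote contrast is significant.
#'
#' @param marker Marker name.
#' @param genotypes A [genotype_matrix()].
#' @param phenos A [phenotype_table()] (rows matched to genotypes by id).
#' @param alpha Significance level applied to adjusted p-values.
#' @param m_tests Bonferroni multiplicity (conventionally the number of
#'   peak markers times the number of phenotypes tested).
#' @param traits Quantitative traits to summarize and test.
#' @param resistant Which allele comes from the EAE-resistant founder
#'   (default `"B"`, the PVG-like allele).
#' @return An `allelic_effect` list: `marker`, `summary` (per-class n,
#'   incidence, trait means/SDs/medians), `tests` (contrast p-values, raw
#'   and adjusted), `classification`, `transgressive`.
#' @export
stratify_and_test <- function(marker, genotypes, phenos, alpha = 0.05,
                              m_tests = 1,
                              traits = c("ONS", "MAX", "DUR", "CUM", "WL"),
                              resistant = c("B", "A")) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(phenos, "phenotype_table"))
  resistant <- match.arg(resistant)
  if (!marker %in% colnames(genotypes)) stop("unknown marker: ", marker)
  ids <- intersect(rownames(genotypes), phenos$id)
  g <- unclass(genotypes)[ids, marker]
  ph <- phenos[match(ids, phenos$id), ]
  keep <- !is.na(g)
  g <- g[keep]; ph <- ph[keep, ]
  classes <- GENO_CODES[GENO_CODES %in% unique(g)]
  if (length(classes) < 2) stop("need >= 2 non-empty genotype classes")
  if (length(classes) < 3) {
    warning("empty genotype class at ", marker, "; two-class testing only")
  }

  summ <- do.call(rbind, lapply(classes, function(cl) {
    rows <- ph[g == cl, ]
    out <- data.frame(class = cl, n = nrow(rows),
                      incidence_pct = incidence_pct(nrow(rows[rows$INC == 1, ]),
                                                    nrow(rows), digits = 1))
    for (tr in traits) {
      v <- rows[[tr]]
      out[[paste0(tr, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(tr, "_sd")]] <- stats::sd(v, na.rm = TRUE)
      out[[paste0(tr, "_median")]] <- stats::median(v, na.rm = TRUE)
    }
    out
  }))

  contrasts <- utils::combn(classes, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(contrasts, function(cc) {
    r1 <- ph[g == cc[1], ]; r2 <- ph[g == cc[2], ]
    rows <- lapply(traits, function(tr) {
      v1 <- r1[[tr]][is.finite(r1[[tr]])]
      v2 <- r2[[tr]][is.finite(r2[[tr]])]
      p <- if (length(v1) && length(v2)) {
        nonparametric_tests(list(v1, v2))$mann_whitney
      } else NA_real_
      data.frame(contrast = paste(cc, collapse = "-"), trait = tr,
                 test = "mann_whitney", p = p, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rbind(rows, data.frame(contrast = paste(cc, collapse = "-"),
                           trait = "INC", test = "fisher_exact",
                           p = fisher_inc(r1$INC, r2$INC),
                           stringsAsFactors = FALSE))
  }))
  kw <- do.call(rbind, lapply(traits, function(tr) {
    gl <- lapply(classes, function(cl) {
      v <- ph[[tr]][g == cl]; v[is.finite(v)]
    })
    p <- if (all(vapply(gl, length, 0L) > 0)) {
      nonparametric_tests(gl)$kruskal_wallis
    } else NA_real_
    data.frame(contrast = "all", trait = tr, test = "kruskal_wallis",
               p = p, stringsAsFactors = FALSE)
  }))
  tests <- rbind(tests, kw)
  tests$p_adj <- bonferroni_adjust(tests$p, m_tests)

  # Classification pools contrast evidence across the whole clinical
  # panel (the minimum adjusted p per contrast), with each trait oriented
  # so that larger means more severe (ONS flipped: earlier onset is more
  # severe).  Direction of a contrast is taken from the trait attaining
  # the minimum p.
  sev_sign <- function(tr) if (tr == "ONS") -1 else 1
  class_mean <- function(cl, tr) {
    row <- summ[summ$class == cl, ]
    if (tr == "INC") row$incidence_pct else row[[paste0(tr, "_mean")]]
  }
  contrast_info <- function(cc) {
    cls <- strsplit(cc, "-", fixed = TRUE)[[1]]
    sub <- tests[tests$contrast == cc & is.finite(tests$p_adj), ]
    if (!nrow(sub)) return(list(p = NA_real_, dir = 0))
    best <- sub[which.min(sub$p_adj), ]
    delta <- (class_mean(cls[2], best$trait) - class_mean(cls[1], best$trait)) *
      sev_sign(best$trait)
    list(p = best$p_adj, dir = sign(delta))
  }
  classification <- "none"
  transgressive <- FALSE
  if (all(GENO_CODES %in% classes)) {
    hom <- contrast_info("AA-BB")     # dir > 0: BB more severe than AA
    ab_aa <- contrast_info("AA-AB")   # dir > 0: AB more severe than AA
    ab_bb <- contrast_info("AB-BB")   # dir > 0: BB more severe than AB
    sig <- function(x) is.finite(x$p) && x$p <= alpha
    if (sig(ab_aa) && sig(ab_bb) && ab_aa$dir == -ab_bb$dir) {
      # AB outside both homozygotes in the same severity direction
      classification <- "heterosis"
    } else if (sig(hom) && sig(ab_aa) && !sig(ab_bb)) {
      classification <- "dominant_B"
    } else if (sig(hom) && sig(ab_bb) && !sig(ab_aa)) {
      classification <- "dominant_A"
    } else if (sig(hom)) {
      classification <- "additive"
    }
    res_dir <- if (resistant == "B") hom$dir else -hom$dir
    # resistant-strain alleles promoting disease = transgressive
    transgressive <- sig(hom) && res_dir > 0
    if (classification == paste0("dominant_", resistant) && res_dir > 0) {
      transgressive <- TRUE
    }
  }

  structure(list(marker = marker, summary = summ, tests = tests,
                 alpha = alpha, m_tests = m_tests,
                 classification = classification,
                 transgressive = isTRUE(unname(transgressive))),
            class = "allelic_effect")
}

#' Genotype-matched congenic phenotype prediction
#'
#' Selects AIL individuals whose genotypes at two loci match the
#' combinations captured in congenic strains and summarizes their
#' phenotypes, predicting what each congenic should look like.  The first
#' combination is the reference (background strain); every other
#' combination is compared against it with Fisher's exact test for
#' incidence and Mann-Whitney for the quantitative traits.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenos A [phenotype_table()].
#' @param locusA,locusB Distinct marker names for the two loci.
#' @param combos Named list of length-2 character vectors
#'   `c(genotype_at_A, genotype_at_B)`; default the three combinations a
#'   congenic program captures (background homozygote, donor homozygote,
#'   heterozygote).
#' @param traits Quantitative traits to summarize.
#' @return Data frame with one row per combination: n, incidence, trait
#'   means, and p-values vs the reference combination (`NA` for the
#'   reference itself or empty combinations).
#' @export
predict_congenic <- function(genotypes, phenos, locusA, locusB,
                             combos = list(DA = c("AA", "AA"),
                                           PVG = c("BB", "BB"),
                                           Het = c("AB", "AB")),
                             traits = c("WL", "ONS", "MAX", "DUR", "CUM")) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(phenos, "phenotype_table"))
  if (identical(locusA, locusB)) stop("locusA and locusB must be distinct markers")
  for (mk in c(locusA, locusB)) {
    if (!mk %in% colnames(genotypes)) stop("unknown marker: ", mk)
  }
  ids <- intersect(rownames(genotypes), phenos$id)
  gA <- unclass(genotypes)[ids, locusA]
  gB <- unclass(genotypes)[ids, locusB]
  ph <- phenos[match(ids, phenos$id), ]

  sel <- lapply(combos, function(cb) {
    which(!is.na(gA) & !is.na(gB) & gA == cb[1] & gB == cb[2])
  })
  ref <- sel[[1]]
  out <- do.call(rbind, lapply(seq_along(combos), function(k) {
    rows <- ph[sel[[k]], ]
    res <- data.frame(combo = names(combos)[k],
                      genoA = combos[[k]][1], genoB = combos[[k]][2],
                      n = nrow(rows),
                      incidence_pct = if (nrow(rows)) incidence_pct(rows, digits = 1) else NA_real_,
                      stringsAsFactors = FALSE)
    for (tr in traits) {
      res[[paste0(tr, "_mean")]] <- if (nrow(rows)) {
        mean(rows[[tr]], na.rm = TRUE)
      } else NA_real_
    }
    res$p_INC <- NA_real_
    for (tr in traits) res[[paste0("p_", tr)]] <- NA_real_
    if (k > 1 && nrow(rows) > 0 && length(ref) > 0) {
      res$p_INC <- fisher_inc(ph$INC[ref], rows$INC)
      for (tr in traits) {
        v1 <- ph[[tr]][ref]; v1 <- v1[is.finite(v1)]
        v2 <- rows[[tr]]; v2 <- v2[is.finite(v2)]
        if (length(v1) && length(v2)) {
          res[[paste0("p_", tr)]] <- nonparametric_tests(list(v1, v2))$mann_whitney
        }
      }
    }
    res
  }))
  rownames(out) <- NULL
  out
}
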