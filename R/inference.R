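# From scans to QTL calls: significance thresholds from family residuals,
# 1.5-LOD support intervals, a two-QTL drop-term fit model, and bootstrap
# localization probabilities.
#
# Conventional genome-wide permutation thresholds are deliberately not the
# primary procedure here: in an AIL the family (sibship) structure breaks
# the exchangeability that trait permutation assumes, so the threshold is
# instead the maximum LOD of a rescan of within-family residuals, with a
# fixed 3.4 cut-off available as a fallback.

#' Family-residual significance threshold
#'
#' Each individual's trait value is replaced by its residual from the
#' family mean and the same scan is repeated on the residuals; the maximum
#' LOD over the region is the trait's significance threshold.  For the
#' binary incidence trait the residual is taken on the 0/1 coding and
#' scanned with the Haley-Knott machinery (residuals of a binary trait
#' are no longer binary).
#'
#' @param trait Trait values, one per grid individual.
#' @param probs A `genoprob_grid`.
#' @param family Family (sibship) id per grid individual; at least two
#'   distinct families are required among non-missing trait values.
#' @param cov Optional [covariate_spec()] passed to the residual scan.
#' @param trait_name Trait label.
#' @param n_rerandom If > 0, additionally average the threshold over this
#'   many random re-assignments of family labels (stability check).
#' @param seed Seed for the re-randomization.
#' @return A `threshold_result` list: `trait`, `threshold`, `method`,
#'   `n_scans`.
#' @export
family_residual_threshold <- function(trait, probs, family, cov = NULL,
                                      trait_name = "trait",
                                      n_rerandom = 0, seed = NULL) {
  rows <- is.finite(trait)
  fam <- as.character(family)
  if (length(fam) != length(trait)) {
    stop("family must have one entry per individual")
  }
  if (length(unique(fam[rows])) < 2) {
    stop("family-residual threshold needs >= 2 families")
  }
  resid_scan <- function(f) {
    res <- trait - stats::ave(trait, f, FUN = function(x) mean(x, na.rm = TRUE))
    if (stats::var(res[rows]) == 0) {
      stop("residuals from family means have zero variance; threshold undefined")
    }
    max(scan_hk(res, probs, cov, trait_name)$lod)
  }
  thr <- resid_scan(fam)
  n_scans <- 1L
  if (n_rerandom > 0) {
    extra <- with_seed(seed, vapply(seq_len(n_rerandom), function(i) {
      resid_scan(sample(fam))
    }, 0))
    thr <- mean(c(thr, extra))
    n_scans <- n_scans + as.integer(n_rerandom)
  }
  structure(list(trait = trait_name, threshold = thr,
                 method = "family_residual", n_scans = n_scans),
            class = "threshold_result")
}

#' Fixed fallback threshold
#'
#' The fixed LOD cut-off of 3.4 suggested by simulation studies for dense
#' intercross scans, used alongside the family-residual threshold.
#'
#' @return A `threshold_result` with `threshold = 3.4`.
#' @export
fallback_threshold <- function() {
  structure(list(trait = NA_character_, threshold = 3.4,
                 method = "fixed_3.4", n_scans = 0L),
            class = "threshold_result")
}

#' 1.5-LOD support interval
#'
#' The interval around a LOD peak bounded by the closest flanking markers
#' whose LOD falls more than `drop` below the peak (the bound is that
#' marker's position); a side with no such marker is clipped at the region
#' end.  Ties at the peak are broken toward the smallest position.
#'
#' @param scan A [scan_result()].
#' @param drop LOD-unit drop defining the interval (default 1.5,
#'   approximately a 95% confidence interval for QTL position in an
#'   intercross).
#' @param peak_index Optional fixed peak index (used when masking out a
#'   previously called QTL); defaults to the global argmax.
#' @return A `support_interval` list: `peak_pos`, `peak_lod`, `lower`,
#'   `upper`, `drop`.
#' @export
support_interval <- function(scan, drop = 1.5, peak_index = NULL) {
  stopifnot(inherits(scan, "scan_result"), nrow(scan) >= 1, drop >= 0)
  pk <- peak_index %||% which.max(scan$lod)
  cut <- scan$lod[pk] - drop
  below <- scan$lod < cut
  lower <- scan$pos_mb[1]
  if (pk > 1) {
    lo <- which(below[seq_len(pk - 1)])
    if (length(lo)) lower <- scan$pos_mb[max(lo)]
  }
  upper <- scan$pos_mb[nrow(scan)]
  if (pk < nrow(scan)) {
    hi <- which(below[(pk + 1):nrow(scan)])
    if (length(hi)) upper <- scan$pos_mb[pk + min(hi)]
  }
  structure(list(peak_pos = scan$pos_mb[pk], peak_lod = scan$lod[pk],
                 lower = lower, upper = upper, drop = drop),
            class = "support_interval")
}

interval_contains <- function(interval, pos) {
  pos >= interval$lower & pos <= interval$upper  # closed on both bounds
}

#' Call up to `max_peaks` QTLs from a single scan
#'
#' Candidate positions are considered in decreasing LOD order; a
#' candidate above the threshold is accepted as a distinct QTL if it
#' lies outside the `drop`-LOD support interval of every
#' already-accepted peak (a supra-threshold peak inside another QTL's
#' interval is part of that QTL's mass).  Each accepted peak's support
#' interval is computed within its basin, delimited by the valley minima
#' separating it from neighbouring accepted peaks.
#'
#' @param scan A [scan_result()].
#' @param threshold LOD threshold a peak must exceed.
#' @param drop Support-interval drop (default 1.5).
#' @param max_peaks Maximum number of QTLs to call (default 2).
#' @return List of `support_interval` objects, ordered by position.
#' @export
find_qtl_peaks <- function(scan, threshold, drop = 1.5, max_peaks = 2) {
  lod <- scan$lod
  accepted <- integer(0)
  for (idx in order(lod, decreasing = TRUE)) {
    if (lod[idx] <= threshold) break
    distinct <- TRUE
    for (a in accepted) {
      si_a <- support_interval(scan, drop, peak_index = a)
      if (interval_contains(si_a, scan$pos_mb[idx])) {
        distinct <- FALSE
        break
      }
    }
    if (distinct) accepted <- c(accepted, idx)
    if (length(accepted) == max_peaks) break
  }
  accepted <- sort(accepted)
  lapply(seq_along(accepted), function(k) {
    pk <- accepted[k]
    blk_lo <- if (k == 1) 1L else {
      v <- seq(accepted[k - 1], pk)
      v[which.min(lod[v])]
    }
    blk_hi <- if (k == length(accepted)) nrow(scan) else {
      v <- seq(pk, accepted[k + 1])
      v[which.min(lod[v])]
    }
    sub <- scan[blk_lo:blk_hi, ]
    class(sub) <- class(scan)
    attributes(sub)[c("trait", "model", "covar", "n")] <-
      attributes(scan)[c("trait", "model", "covar", "n")]
    support_interval(sub, drop, peak_index = pk - blk_lo + 1L)
  })
}

grid_index_at <- function(probs, pos) {
  grid <- attr(probs, "pos_mb")
  i <- which.min(abs(grid - pos))
  if (abs(grid[i] - pos) > 1e-6) {
    message(sprintf("position %.3f Mb not on the grid; using %.3f Mb",
                    pos, grid[i]))
  }
  i
}

#' Two-QTL fit model with drop-term tests
#'
#' Fits phenotype ~ QTL_A + QTL_B (+ covariates), each QTL entering with
#' its additive and dominance regressor, and tests each locus by dropping
#' its two terms: an F test under Haley-Knott, a likelihood-ratio
#' chi-square (2 df) under the binary model.  Establishes that the two
#' loci have independent effects.
#'
#' @param trait Trait values per grid individual (0/1 for `model =
#'   "binary"`).
#' @param probs A `genoprob_grid`.
#' @param posA,posB Distinct positions (Mb) of the two loci; snapped to
#'   the nearest grid position.
#' @param cov Optional [covariate_spec()].
#' @param model `"hk"` or `"binary"`.
#' @return Data frame with one row per locus: position, drop-term
#'   p-value, variance (or deviance) share, and a significance annotation
#'   (`**` p < 0.01, `*` p < 0.05, `""`).
#' @export
fit_two_qtl <- function(trait, probs, posA, posB, cov = NULL,
                        model = c("hk", "binary")) {
  model <- match.arg(model)
  if (isTRUE(all.equal(posA, posB))) stop("posA and posB must differ")
  iA <- grid_index_at(probs, posA)
  iB <- grid_index_at(probs, posB)
  if (iA == iB) stop("posA and posB resolve to the same grid position")
  rows <- which(is.finite(trait))
  y <- trait[rows]
  QA <- dosage_at(probs, iA, rows); colnames(QA) <- c("aA", "dA")
  QB <- dosage_at(probs, iB, rows); colnames(QB) <- c("aB", "dB")
  if (abs(stats::cor(QA[, 1], QB[, 1])) > 0.999) {
    stop("genotype dosages at the two loci are collinear; use wider spacing")
  }
  C <- if (is.null(cov)) NULL else cov$values[rows, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  Xfull <- cbind(X0, QA, QB)
  n <- length(y)
  res <- data.frame(locus = c("A", "B"),
                    pos_mb = c(attr(probs, "pos_mb")[iA],
                               attr(probs, "pos_mb")[iB]),
                    p_value = NA_real_, share = NA_real_,
                    signif = "", stringsAsFactors = FALSE)
  if (model == "hk") {
    if (stats::var(y) == 0) stop("trait has zero variance")
    rss_full <- rss_fit(Xfull, y)
    tss <- sum((y - mean(y))^2)
    df_full <- n - ncol(Xfull)
    for (k in 1:2) {
      Xdrop <- cbind(X0, if (k == 1) QB else QA)
      rss_drop <- rss_fit(Xdrop, y)
      Fstat <- ((rss_drop - rss_full) / 2) / (rss_full / df_full)
      res$p_value[k] <- stats::pf(Fstat, 2, df_full, lower.tail = FALSE)
      res$share[k] <- (rss_drop - rss_full) / tss
    }
  } else {
    if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
      stop("binary model needs a 0/1 trait with both classes present")
    }
    ll_full <- logistic_loglik(Xfull, y)$loglik
    ll_null <- logistic_loglik(X0, y)$loglik
    for (k in 1:2) {
      Xdrop <- cbind(X0, if (k == 1) QB else QA)
      ll_drop <- logistic_loglik(Xdrop, y)$loglik
      lr <- 2 * (ll_full - ll_drop)
      res$p_value[k] <- stats::pchisq(max(lr, 0), 2, lower.tail = FALSE)
      res$share[k] <- max(lr, 0) / max(2 * (ll_full - ll_null), .Machine$double.eps)
    }
  }
  res$signif <- ifelse(res$p_value < 0.01, "**",
                       ifelse(res$p_value < 0.05, "*", ""))
  res
}

subset_grid <- function(probs, idx) {
  out <- probs[idx, , , drop = FALSE]
  attr(out, "pos_mb") <- attr(probs, "pos_mb")
  attr(out, "expansion") <- attr(probs, "expansion")
  class(out) <- "genoprob_grid"
  out
}

#' Bootstrap QTL localization probability
#'
#' Simulated pedigrees are drawn by resampling individuals with
#' replacement (same n) and each resample is mapped with a single-QTL
#' scan, forcing closely linked QTLs to compete for effect.  The
#' localization probability of a support interval is the percentage of
#' replicates whose supra-threshold maximum LOD lands inside it (closed
#' bounds).
#'
#' @param trait Trait values per grid individual.
#' @param probs A `genoprob_grid`.
#' @param intervals List of `support_interval` objects; a warning is
#'   emitted if they overlap.
#' @param threshold LOD threshold a replicate's maximum must exceed to be
#'   assigned to an interval.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @param model `"hk"` or `"binary"`.
#' @param cov Optional [covariate_spec()].
#' @param count_subthreshold If `TRUE` (default) replicates whose maximum
#'   LOD fails the threshold stay in the denominator; if `FALSE` the
#'   probability is conditional on exceeding the threshold.
#' @return Numeric vector of percentages, one per interval, plus
#'   attribute `n_above` (replicates exceeding the threshold).
#' @export
localization_probability <- function(trait, probs, intervals, threshold,
                                     n_boot = 1000, seed = NULL,
                                     model = c("hk", "binary"), cov = NULL,
                                     count_subthreshold = TRUE) {
  model <- match.arg(model)
  if (n_boot < 1) stop("n_boot must be >= 1")
  stopifnot(length(intervals) >= 1)
  for (i in seq_along(intervals)) {
    for (j in seq_len(i - 1)) {
      if (intervals[[i]]$lower <= intervals[[j]]$upper &&
          intervals[[j]]$lower <= intervals[[i]]$upper) {
        warning("support intervals overlap; a replicate can only be assigned to one")
      }
    }
  }
  scan_fun <- if (model == "hk") scan_hk else scan_binary
  n <- dim(probs)[1]
  hits <- integer(length(intervals))
  n_above <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      tb <- trait[idx]
      if (model == "hk" &&
          (sum(is.finite(tb)) < 8 || stats::var(tb[is.finite(tb)]) == 0)) next
      if (model == "binary" && length(unique(tb[is.finite(tb)])) < 2) next
      covb <- if (is.null(cov)) NULL else {
        structure(list(name = cov$name,
                       values = cov$values[idx, , drop = FALSE],
                       role = cov$role), class = "covariate_spec")
      }
      sc <- suppressWarnings(scan_fun(tb, subset_grid(probs, idx), covb))
      mx <- which.max(sc$lod)
      if (sc$lod[mx] > threshold) {
        n_above <- n_above + 1L
        pos <- sc$pos_mb[mx]
        for (i in seq_along(intervals)) {
          if (interval_contains(intervals[[i]], pos)) {
            hits[i] <- hits[i] + 1L
            break
          }
        }
      }
    }
  })
  denom <- if (count_subthreshold) n_boot else max(n_above, 1L)
  out <- 100 * hits / denom
  names(out) <- paste0("interval", seq_along(intervals))
  attr(out, "n_above") <- n_above
  out
}
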