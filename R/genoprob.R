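# Conditional genotype-class probabilities on a scan grid.
#
# Probabilities at a position are computed from the nearest informative
# (non-missing) flanking markers under a two-locus Markov model on each of
# the two chromosomes, with Haldane recombination fractions on the cM
# scale.  AIL recombination accumulation enters as a map-expansion factor
# applied to cM distances before the Haldane transform, which keeps the
# per-chromosome transition matrices consistent under composition.

# 2x2 allele transition matrix for recombination fraction r.
trans2 <- function(r) matrix(c(1 - r, r, r, 1 - r), 2, 2)

# Ordered haplotype-pair configurations consistent with an unordered
# genotype class (0 = AA, 1 = AB, 2 = BB); alleles coded 0 = A, 1 = B.
ordered_configs <- function(g) {
  switch(as.character(g),
         "0" = list(c(0L, 0L)),
         "1" = list(c(0L, 1L), c(1L, 0L)),
         "2" = list(c(1L, 1L)))
}

# P(AA, AB, BB) at an interior position given unordered genotype classes
# gL, gR at the flanks, with recombination fractions rL (left-position),
# rR (position-right) and rLR (left-right).
bridge_triple <- function(gL, gR, rL, rR, rLR) {
  TL <- trans2(rL); TR <- trans2(rR); TLR <- trans2(rLR)
  out <- c(0, 0, 0)
  wtot <- 0
  for (cl in ordered_configs(gL)) {
    for (cr in ordered_configs(gR)) {
      w <- TLR[cl[1] + 1, cr[1] + 1] * TLR[cl[2] + 1, cr[2] + 1]
      if (w <= 0) next
      pB <- vapply(1:2, function(ch) {
        num <- TL[cl[ch] + 1, 2] * TR[2, cr[ch] + 1]
        den <- TLR[cl[ch] + 1, cr[ch] + 1]
        num / den
      }, 0)
      pA <- 1 - pB
      out <- out + w * c(pA[1] * pA[2],
                         pA[1] * pB[2] + pB[1] * pA[2],
                         pB[1] * pB[2])
      wtot <- wtot + w
    }
  }
  out / wtot
}

# One-sided version: only a single informative marker at recombination
# fraction r from the position.
side_triple <- function(g, r) {
  pBs <- switch(as.character(g),
                "0" = c(r, r),
                "1" = c(r, 1 - r),
                "2" = c(1 - r, 1 - r))
  pA <- 1 - pBs
  c(pA[1] * pA[2], pA[1] * pBs[2] + pBs[1] * pA[2], pBs[1] * pBs[2])
}

#' Conditional genotype probabilities at scan positions
#'
#' For every individual and every scan position, computes the probability
#' of each genotype class (`AA`, `AB`, `BB`) given the nearest informative
#' flanking marker genotypes.  Missing marker genotypes are skipped in the
#' flank search; positions beyond the terminal informative markers
#' condition on the single nearest marker; individuals with no typed
#' marker at all receive the intercross prior (1/4, 1/2, 1/4) with a
#' warning.
#'
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()]; cM positions derived at
#'   `cm_per_mb` if absent.
#' @param step Pseudo-position grid step in Mb; `0` (default) scans at the
#'   markers only.
#' @param expansion Map-expansion multiplier (>= 1) applied to cM
#'   distances; the AIL expectation for generation `t` is `t/2`.
#' @param cm_per_mb Mb-to-cM rate used if the map lacks `pos_cm`.
#' @return A `genoprob_grid`: an `n x positions x 3` array with attributes
#'   `pos_mb`, `expansion`.
#' @export
conditional_probabilities <- function(genotypes, map, step = 0, expansion = 1,
                                      cm_per_mb = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  map <- as_genetic_map(map)
  if (is.null(map$pos_cm)) map <- derive_cm_positions(map, cm_per_mb)
  if (!identical(colnames(genotypes), map$marker)) {
    stop("genotype columns must match the map's markers")
  }
  if (step < 0) stop("step must be >= 0")
  if (expansion < 1) stop("expansion must be >= 1")

  pos_mb <- map$pos_mb
  if (step > 0) {
    grid_mb <- sort(unique(c(pos_mb,
                             seq(min(pos_mb), max(pos_mb), by = step))))
  } else {
    grid_mb <- pos_mb
  }
  rate <- (max(map$pos_cm) - min(map$pos_cm)) /
    (max(pos_mb) - min(pos_mb))
  grid_cm <- min(map$pos_cm) + (grid_mb - min(pos_mb)) * rate
  mk_cm <- map$pos_cm

  n <- nrow(genotypes)
  P <- length(grid_mb)
  g_num <- matrix(match(unclass(genotypes), GENO_CODES) - 1L, nrow = n)
  probs <- array(NA_real_, dim = c(n, P, 3),
                 dimnames = list(rownames(genotypes), NULL, GENO_CODES))

  no_info <- rowSums(!is.na(g_num)) == 0
  if (any(no_info)) {
    warning(sum(no_info), " individual(s) with all markers missing; ",
            "using the (1/4, 1/2, 1/4) prior")
  }

  typed <- !is.na(g_num)
  for (p in seq_len(P)) {
    pc <- grid_cm[p]
    # nearest informative flank indices per individual
    left_mk <- rev(which(mk_cm <= pc + 1e-9))
    right_mk <- which(mk_cm >= pc - 1e-9)
    Lidx <- rep(NA_integer_, n); Ridx <- rep(NA_integer_, n)
    for (j in left_mk) {  # descending from the position
      fill <- is.na(Lidx) & typed[, j]
      Lidx[fill] <- j
      if (!anyNA(Lidx)) break
    }
    for (j in right_mk) {
      fill <- is.na(Ridx) & typed[, j]
      Ridx[fill] <- j
      if (!anyNA(Ridx)) break
    }
    key <- paste(Lidx, Ridx,
                 ifelse(is.na(Lidx), -1L, g_num[cbind(seq_len(n), ifelse(is.na(Lidx), 1L, Lidx))]),
                 ifelse(is.na(Ridx), -1L, g_num[cbind(seq_len(n), ifelse(is.na(Ridx), 1L, Ridx))]))
    for (k in unique(key)) {
      rows <- which(key == k)
      i <- rows[1]
      li <- Lidx[i]; ri <- Ridx[i]
      tri <- if (is.na(li) && is.na(ri)) {
        c(0.25, 0.5, 0.25)
      } else if (!is.na(li) && !is.na(ri) && li == ri) {
        out <- c(0, 0, 0); out[g_num[i, li] + 1L] <- 1; out
      } else if (is.na(ri)) {
        side_triple(g_num[i, li], expanded_rf(pc - mk_cm[li], expansion))
      } else if (is.na(li)) {
        side_triple(g_num[i, ri], expanded_rf(mk_cm[ri] - pc, expansion))
      } else {
        bridge_triple(g_num[i, li], g_num[i, ri],
                      expanded_rf(pc - mk_cm[li], expansion),
                      expanded_rf(mk_cm[ri] - pc, expansion),
                      expanded_rf(mk_cm[ri] - mk_cm[li], expansion))
      }
      probs[rows, p, 1] <- tri[1]
      probs[rows, p, 2] <- tri[2]
      probs[rows, p, 3] <- tri[3]
    }
  }
  structure(probs, pos_mb = grid_mb, expansion = expansion,
            class = "genoprob_grid")
}

#' Dump / restore a genotype-probability grid
#'
#' Long-format delimited file (`id`, `pos_mb`, `pAA`, `pAB`, `pBB`) for
#' debugging and inspection.
#'
#' @param grid A `genoprob_grid`.
#' @param path File path.
#' @return `read_genoprob()` returns a `genoprob_grid`.
#' @export
write_genoprob <- function(grid, path) {
  stopifnot(inherits(grid, "genoprob_grid"))
  pos <- attr(grid, "pos_mb")
  ids <- dimnames(grid)[[1]]
  df <- data.frame(id = rep(ids, times = length(pos)),
                   pos_mb = rep(pos, each = length(ids)),
                   pAA = as.vector(grid[, , 1]),
                   pAB = as.vector(grid[, , 2]),
                   pBB = as.vector(grid[, , 3]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genoprob
#' @export
read_genoprob <- function(path) {
  df <- read_table_checked(path)
  ids <- unique(df$id)
  pos <- sort(unique(df$pos_mb))
  arr <- array(NA_real_, dim = c(length(ids), length(pos), 3),
               dimnames = list(ids, NULL, GENO_CODES))
  i <- match(df$id, ids)
  p <- match(df$pos_mb, pos)
  arr[cbind(i, p, 1L)] <- df$pAA
  arr[cbind(i, p, 2L)] <- df$pAB
  arr[cbind(i, p, 3L)] <- df$pBB
  structure(arr, pos_mb = pos, expansion = NA_real_, class = "genoprob_grid")
}
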