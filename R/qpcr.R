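# Relative quantification of qPCR expression by the delta-delta-Ct
# method, assuming perfect doubling per cycle (amplification efficiencies
# of target and reference approximately equivalent).

#' Construct a Ct table
#'
#' @param sample Sample identifiers.
#' @param group Group label per sample (e.g. strain).
#' @param ct_target Target-gene threshold cycles.
#' @param ct_ref Reference-gene threshold cycles (required for every
#'   sample).
#' @return A `ct_table` data frame.
#' @export
ct_table <- function(sample, group, ct_target, ct_ref) {
  df <- data.frame(sample = as.character(sample),
                   group = as.character(group),
                   ct_target = as.numeric(ct_target),
                   ct_ref = as.numeric(ct_ref),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("Ct table is empty")
  if (any(!is.finite(df$ct_ref))) stop("reference Ct missing for some samples")
  if (any(!is.finite(df$ct_target))) stop("target Ct missing for some samples")
  soft <- c(df$ct_target, df$ct_ref)
  if (any(soft < 10 | soft > 40)) {
    warning("Ct values outside the typical 10-40 cycle range")
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a Ct table file
#'
#' Columns `sample`, `group`, `ct_target`, `ct_ref`.
#'
#' @param path File path.
#' @return A [ct_table()].
#' @export
read_ct <- function(path) {
  df <- read_table_checked(path)
  need <- c("sample", "group", "ct_target", "ct_ref")
  if (!all(need %in% names(df))) {
    stop(path, ": Ct file must have columns ", paste(need, collapse = ", "))
  }
  ct_table(df$sample, df$group, df$ct_target, df$ct_ref)
}

#' Relative quantity by delta-delta-Ct
#'
#' Per sample, `dCt = Ct_target - Ct_ref`; `ddCt` centres `dCt` on the
#' mean `dCt` of the calibrator set (all samples by default, or one named
#' group); `RQ = 2^(-ddCt)`.  The geometric mean of RQ over the
#' calibrator set is exactly 1.
#'
#' @param table A [ct_table()].
#' @param calibrator_group Optional group label to use as the calibrator
#'   set; default all samples.
#' @return The table with added columns `dct`, `ddct`, `rq`.
#' @export
relative_quantity <- function(table, calibrator_group = NULL) {
  stopifnot(inherits(table, "ct_table"))
  dct <- table$ct_target - table$ct_ref
  cal <- if (is.null(calibrator_group)) {
    rep(TRUE, nrow(table))
  } else {
    table$group == calibrator_group
  }
  if (!any(cal)) stop("calibrator group has no samples: ", calibrator_group)
  table$dct <- dct
  table$ddct <- dct - mean(dct[cal])
  table$rq <- 2^(-table$ddct)
  table
}

#' Compare RQ between two groups
#'
#' Mann-Whitney U comparison of relative quantities, delegating to
#' [nonparametric_tests()].
#'
#' @param rq Relative quantities.
#' @param groups Group label per value; exactly two distinct groups.
#' @return Two-sided Mann-Whitney p-value.
#' @export
group_compare_rq <- function(rq, groups) {
  g <- unique(groups)
  if (length(g) != 2) stop("need exactly two groups")
  split_rq <- split(rq, factor(groups, levels = g))
  if (length(split_rq[[1]]) == 1 && length(split_rq[[2]]) == 1) return(1)
  nonparametric_tests(split_rq)$mann_whitney
}
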