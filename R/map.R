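#' Construct a genetic map
#'
#' A genetic map is an ordered table of markers on a single labelled
#' chromosome region, with physical positions in megabases.  Positions must
#' be strictly increasing and marker names unique.
#'
#' @param marker Character vector of unique marker names.
#' @param chr Chromosome label (single value or one per marker).
#' @param pos_mb Numeric physical positions in Mb, strictly increasing,
#'   non-negative.
#' @return A `genetic_map` data frame with columns `marker`, `chr`, `pos_mb`.
#' @examples
#' genetic_map(c("M1", "M2"), "17", c(13.9, 81.6))
#' @export
genetic_map <- function(marker, chr, pos_mb) {
  marker <- as.character(marker)
  pos_mb <- as.numeric(pos_mb)
  if (anyDuplicated(marker)) {
    stop("duplicate marker names: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  if (any(!is.finite(pos_mb)) || any(pos_mb < 0)) {
    stop("marker positions must be finite and >= 0")
  }
  if (length(pos_mb) > 1 && any(diff(pos_mb) <= 0)) {
    bad <- which(diff(pos_mb) <= 0)[1]
    stop(sprintf(
      "map positions must be strictly increasing: %s (%.4g Mb) !< %s (%.4g Mb)",
      marker[bad], pos_mb[bad], marker[bad + 1], pos_mb[bad + 1]))
  }
  out <- data.frame(marker = marker,
                    chr = as.character(rep_len(chr, length(marker))),
                    pos_mb = pos_mb,
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Attach genetic (cM) positions to a map
#'
#' The pipeline maps on physical positions, so the genetic scale used for
#' recombination modelling has to be made explicit.  Positions are converted
#' at a uniform rate, `cM = Mb * rate` (default 1 cM/Mb).
#'
#' @param map A [genetic_map()].
#' @param rate Recombination rate in cM/Mb, strictly positive.
#' @return The map with an added `pos_cm` column.
#' @export
derive_cm_positions <- function(map, rate = 1) {
  map <- as_genetic_map(map)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number (cM/Mb)")
  }
  map$pos_cm <- map$pos_mb * rate
  map
}

# Validate/coerce an object to a genetic_map (re-checks invariants).
as_genetic_map <- function(x) {
  if (!is.data.frame(x) || !all(c("marker", "chr", "pos_mb") %in% names(x))) {
    stop("expected a genetic map with columns marker, chr, pos_mb")
  }
  out <- genetic_map(x$marker, x$chr, x$pos_mb)
  if ("pos_cm" %in% names(x)) out$pos_cm <- as.numeric(x$pos_cm)
  out
}

#' Physical span of a genetic map
#'
#' @param map A [genetic_map()].
#' @return Span in Mb between the first and last marker.
#' @examples
#' map_span(genetic_map(c("a", "b"), "17", c(13.9, 81.6)))  # 67.7
#' @export
map_span <- function(map) {
  map <- as_genetic_map(map)
  max(map$pos_mb) - min(map$pos_mb)
}
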