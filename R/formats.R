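# Delimited-file dialects for the four pipeline tables.
#
# All files are UTF-8, comma-delimited, decimal point, mandatory header row.
# The missing-genotype token defaults to "-".  Parsers reject malformed
# input with file/line context; they never silently coerce.

#' Construct a genotype matrix
#'
#' Per-individual marker genotypes in a three-class coding: `AA` and `BB`
#' are the two parental homozygotes (A = DA allele, B = PVG allele), `AB`
#' the heterozygote, `NA` missing.
#'
#' @param x Character matrix with individual ids as row names and marker
#'   names as column names; cells in `AA`/`AB`/`BB`/`NA`.
#' @param map Optional [genetic_map()]; if given, columns must match its
#'   markers in order.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(x, map = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("genotype matrix needs individual ids as rownames and markers as colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(x))) stop("duplicate marker names")
  mode(x) <- "character"
  bad <- !is.na(x) & !(x %in% GENO_CODES)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype token '%s' (individual %s, marker %s)",
                 x[bad][1], rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  if (!is.null(map)) {
    map <- as_genetic_map(map)
    if (!identical(colnames(x), map$marker)) {
      stop("genotype columns do not match the map's markers (same order required)")
    }
  }
  class(x) <- c("genotype_matrix", class(x))
  x
}

#' Construct a phenotype table
#'
#' Per-individual EAE traits: `INC` binary incidence, `ONS` day of onset
#' post-immunization (defined only if affected), `MAX` maximum clinical
#' score (0-4 scale), `DUR` days with symptoms, `CUM` cumulative score and
#' `WL` percent weight loss, plus `sex` (`F`/`M`) and a `family` (sibship)
#' id.  Unaffected animals have `ONS = NA` and `DUR = CUM = 0`.
#'
#' @param df Data frame with columns `id`, `sex`, `family`, `INC`, `ONS`,
#'   `MAX`, `DUR`, `CUM`, `WL`.
#' @return A `phenotype_table` data frame.
#' @export
phenotype_table <- function(df) {
  need <- c("id", "sex", "family", "INC", "ONS", "MAX", "DUR", "CUM", "WL")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing columns: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  df <- as.data.frame(df)[c(need, extra)]
  df$id <- as.character(df$id)
  df$family <- as.character(df$family)
  if (anyDuplicated(df$id)) stop("duplicate individual ids in phenotype table")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  for (v in c("INC", "ONS", "MAX", "DUR", "CUM", "WL")) {
    df[[v]] <- as.numeric(df[[v]])
  }
  if (!all(df$INC %in% c(0, 1))) stop("INC must be 0/1")
  unaff <- df$INC == 0
  if (any(!is.na(df$ONS[unaff]))) stop("ONS must be NA for unaffected (INC = 0)")
  if (any(df$DUR[unaff] != 0) || any(df$CUM[unaff] != 0)) {
    stop("DUR and CUM must be 0 for unaffected (INC = 0)")
  }
  if (any(df$MAX < 0, na.rm = TRUE)) stop("MAX must be >= 0")
  if (any(df$DUR < 0 | df$DUR > 35, na.rm = TRUE)) {
    stop("DUR must lie in [0, 35] (observation window)")
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Construct a scan result
#'
#' @param pos_mb Ordered positions (Mb).
#' @param lod Non-negative finite LOD scores, one per position.
#' @param trait Trait name.
#' @param model `"haley_knott"` or `"binary"`.
#' @param covar Covariate specification tag (e.g. `"none"`,
#'   `"sex:additive"`).
#' @param n Number of individuals used.
#' @return A `scan_result` data frame with columns `pos_mb`, `lod` and
#'   metadata attributes `trait`, `model`, `covar`, `n`.
#' @export
scan_result <- function(pos_mb, lod, trait, model, covar = "none", n = NA_integer_) {
  stopifnot(length(pos_mb) == length(lod))
  if (is.unsorted(pos_mb, strictly = TRUE)) stop("scan positions must be increasing")
  if (!model %in% c("haley_knott", "binary")) stop("unknown model tag: ", model)
  if (any(!is.finite(lod)) || any(lod < -1e-8)) {
    stop("LOD scores must be finite and >= 0")
  }
  out <- data.frame(pos_mb = as.numeric(pos_mb), lod = pmax(0, as.numeric(lod)))
  attr(out, "trait") <- as.character(trait)
  attr(out, "model") <- model
  attr(out, "covar") <- as.character(covar)
  attr(out, "n") <- as.integer(n)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Scan of %s (%s model, covariates: %s, n = %d)\n",
              attr(x, "trait"), attr(x, "model"), attr(x, "covar"), attr(x, "n")))
  cat(sprintf("  %d positions, max LOD %.3f at %.2f Mb\n",
              nrow(x), max(x$lod), x$pos_mb[which.max(x$lod)]))
  invisible(x)
}

# --- readers/writers ---------------------------------------------------

read_table_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = NA)
}

#' Read / write a genetic map file
#'
#' Columns `marker`, `chr`, `pos_mb` (and `pos_cm` if present).
#'
#' @param path File path.
#' @param map A [genetic_map()] to write.
#' @return `read_map()` returns a `genetic_map`; `write_map()` the path,
#'   invisibly.
#' @export
read_map <- function(path) {
  df <- read_table_checked(path)
  need <- c("marker", "chr", "pos_mb")
  if (!all(need %in% names(df))) {
    stop(path, ": map file must have columns ", paste(need, collapse = ", "))
  }
  map <- tryCatch(genetic_map(df$marker, df$chr, as.numeric(df$pos_mb)),
                  error = function(e) stop(path, ": ", conditionMessage(e),
                                           call. = FALSE))
  if ("pos_cm" %in% names(df)) map$pos_cm <- as.numeric(df$pos_cm)
  map
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  map <- as_genetic_map(map)
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a genotype matrix file
#'
#' First column `id`, then one column per marker; missing genotypes written
#' with `missing_token`.
#'
#' @param path File path.
#' @param geno A [genotype_matrix()] to write.
#' @param missing_token Token used for missing genotypes (default `"-"`).
#' @return `read_genotypes()` returns a `genotype_matrix`.
#' @export
read_genotypes <- function(path, missing_token = "-") {
  df <- read_table_checked(path)
  if (names(df)[1] != "id") stop(path, ": first column must be 'id'")
  ids <- as.character(df$id)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "character"
  rownames(m) <- ids
  bad <- !(m %in% c(GENO_CODES, missing_token)) & !is.na(m)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "%s: invalid genotype token '%s' at data row %d (id %s), column '%s'",
      path, m[bad][1], idx[1], ids[idx[1]], colnames(m)[idx[2]]))
  }
  m[m == missing_token] <- NA_character_
  genotype_matrix(m)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(geno, path, missing_token = "-") {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- unclass(geno)
  m[is.na(m)] <- missing_token
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype table file
#'
#' @param path File path.
#' @param phenos A [phenotype_table()] to write.
#' @return `read_phenotypes()` returns a `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- read_table_checked(path)
  tryCatch(phenotype_table(df),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenos, path) {
  stopifnot(inherits(phenos, "phenotype_table"))
  utils::write.csv(as.data.frame(phenos), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a scan-result file
#'
#' Metadata (trait, model, covariates, n) is carried in `# key: value`
#' comment lines ahead of the header.
#'
#' @param path File path.
#' @param scan A [scan_result()] to write.
#' @return `read_scan()` returns a `scan_result`.
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- read_table_checked(path)
  scan_result(as.numeric(df$pos_mb), as.numeric(df$lod),
              trait = meta$trait %||% "unknown",
              model = meta$model %||% "haley_knott",
              covar = meta$covar %||% "none",
              n = as.integer(meta$n %||% NA))
}

#' @rdname read_scan
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s",
                     c("trait", "model", "covar", "n"),
                     c(attr(scan, "trait"), attr(scan, "model"),
                       attr(scan, "covar"), attr(scan, "n"))), con)
  utils::write.csv(as.data.frame(scan), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- derived phenotype arithmetic --------------------------------------

#' Percent weight loss from a daily weight series
#'
#' Weight loss is the drop from the weight at immunization (day 0) to the
#' lowest weight observed, expressed as a percentage of the initial weight.
#' The minimum is taken over the series including day 0, so animals that
#' only gain weight get `WL = 0` rather than a negative value.
#'
#' @param weights Numeric per-day weight series (g), day 0 onwards.
#' @param day0_weight Weight at immunization (g), strictly positive; by
#'   default the first element of `weights`.
#' @return Weight loss in percent.
#' @examples
#' compute_wl(c(200, 195, 180, 190))  # 10
#' @export
compute_wl <- function(weights, day0_weight = weights[1]) {
  if (!length(weights)) stop("weight series is empty")
  if (!is.finite(day0_weight) || day0_weight <= 0) {
    stop("initial weight must be positive")
  }
  100 * (day0_weight - min(c(day0_weight, weights))) / day0_weight
}

#' Cohort incidence in percent
#'
#' @param phenos A [phenotype_table()], or a count of affected individuals
#'   if `n_total` is given.
#' @param n_total Optional total count when passing raw counts.
#' @param digits Rounding applied to the percentage (default 0, matching
#'   cohort-level reporting).
#' @return Incidence as a percentage.
#' @examples
#' incidence_pct(224, 772)  # 29
#' @export
incidence_pct <- function(phenos, n_total = NULL, digits = 0) {
  if (is.null(n_total)) {
    stopifnot(inherits(phenos, "phenotype_table"))
    affected <- sum(phenos$INC == 1)
    n_total <- nrow(phenos)
  } else {
    affected <- as.numeric(phenos)
  }
  if (n_total <= 0) stop("total count must be positive")
  round(100 * affected / n_total, digits)
}

#' Summarize a phenotype table
#'
#' Cohort-level summary used in pipeline reports: counts, incidence, and
#' per-trait means among affected individuals.
#'
#' @param phenos A [phenotype_table()].
#' @return Data frame with one row per cohort statistic.
#' @export
summarize_phenotypes <- function(phenos) {
  stopifnot(inherits(phenos, "phenotype_table"))
  aff <- phenos[phenos$INC == 1, ]
  data.frame(
    n = nrow(phenos),
    n_affected = nrow(aff),
    incidence_pct = incidence_pct(phenos),
    mean_ONS = mean(aff$ONS),
    mean_MAX = mean(aff$MAX),
    mean_DUR = mean(aff$DUR),
    mean_CUM = mean(aff$CUM),
    mean_WL = mean(phenos$WL)
  )
}
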