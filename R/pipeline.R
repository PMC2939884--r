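# End-to-end orchestration: tables -> genotype probabilities -> scans ->
# thresholds -> support intervals -> two-QTL fit -> bootstrap
# localization -> allelic effects, emitting a per-trait QTL report.

#' Configure a pipeline run
#'
#' Inputs may be given as in-memory objects (`map`, `genotypes`,
#' `phenotypes`) or as file paths in the package's delimited dialects
#' (`map_file`, `genotype_file`, `phenotype_file`).
#'
#' @param map,genotypes,phenotypes In-memory inputs.
#' @param map_file,genotype_file,phenotype_file File-path inputs.
#' @param traits Traits to scan (default `INC` plus the quantitative
#'   panel).
#' @param sex_filter Restrict the analysis to one sex (`"F"`, `"M"`) or
#'   `NULL` for all animals.
#' @param sex_covar Sex covariate role when both sexes are analyzed:
#'   `"none"`, `"additive"` or `"interactive"`.
#' @param expansion AIL map-expansion factor for the probability grid.
#' @param step Pseudo-position step in Mb (0 = markers only).
#' @param threshold_method `"family_residual"` or `"fixed_3.4"`.
#' @param threshold_floor Reported QTLs must exceed
#'   `max(threshold, threshold_floor)`.
#' @param drop Support-interval LOD drop (default 1.5).
#' @param n_boot Bootstrap replicates for localization probabilities.
#' @param alpha,m_tests Significance level and Bonferroni multiplicity
#'   for allelic-effect testing (`m_tests = NULL`: number of peak markers
#'   times number of phenotypes, decided after peak calling).
#' @param max_peaks Maximum QTLs called per trait (default 2).
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional directory for the report and intermediate
#'   files.
#' @return A `run_config` list.
#' @export
run_config <- function(map = NULL, genotypes = NULL, phenotypes = NULL,
                       map_file = NULL, genotype_file = NULL,
                       phenotype_file = NULL,
                       traits = c("INC", "MAX", "DUR", "CUM", "WL"),
                       sex_filter = "F", sex_covar = "none",
                       expansion = 5, step = 0,
                       threshold_method = c("family_residual", "fixed_3.4"),
                       threshold_floor = 0, drop = 1.5, n_boot = 1000,
                       alpha = 0.05, m_tests = NULL, max_peaks = 2,
                       seed = 1, out_dir = NULL) {
  threshold_method <- match.arg(threshold_method)
  for (f in c(map_file, genotype_file, phenotype_file)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  if (is.null(map) && is.null(map_file)) stop("a map (object or file) is required")
  if (is.null(genotypes) && is.null(genotype_file)) stop("genotypes required")
  if (is.null(phenotypes) && is.null(phenotype_file)) stop("phenotypes required")
  structure(list(map = map, genotypes = genotypes, phenotypes = phenotypes,
                 map_file = map_file, genotype_file = genotype_file,
                 phenotype_file = phenotype_file, traits = traits,
                 sex_filter = sex_filter, sex_covar = sex_covar,
                 expansion = expansion, step = step,
                 threshold_method = threshold_method,
                 threshold_floor = threshold_floor, drop = drop,
                 n_boot = as.integer(n_boot), alpha = alpha,
                 m_tests = m_tests, max_peaks = as.integer(max_peaks),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

nearest_marker <- function(map, pos) {
  map$marker[which.min(abs(map$pos_mb - pos))]
}

#' Run the full QTL-calling pipeline
#'
#' For every configured trait: single-QTL scan (binary logistic for
#' `INC`, Haley-Knott otherwise), significance threshold, peak calling
#' with `drop`-LOD support intervals, bootstrap localization
#' probabilities, a two-QTL drop-term fit when two peaks are called, and
#' allelic-effect classification at each peak marker.
#'
#' @param config A [run_config()].
#' @return List with `report` (one row per trait and called QTL),
#'   `scans`, `thresholds`, `effects` (per peak marker), `fits`, and the
#'   inputs used.  If `config$out_dir` is set, the report, scans and a
#'   run log are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  map <- config$map %||% read_map(config$map_file)
  map <- as_genetic_map(map)
  geno <- config$genotypes %||% read_genotypes(config$genotype_file)
  phen <- config$phenotypes %||% read_phenotypes(config$phenotype_file)
  stopifnot(inherits(geno, "genotype_matrix"), inherits(phen, "phenotype_table"))

  ids <- intersect(rownames(geno), phen$id)
  if (!length(ids)) stop("no shared individual ids between genotypes and phenotypes")
  phen <- phen[match(ids, phen$id), ]
  geno <- genotype_matrix(unclass(geno)[ids, , drop = FALSE], map)
  if (!is.null(config$sex_filter)) {
    keep <- phen$sex == config$sex_filter
    phen <- phen[keep, ]
    geno <- genotype_matrix(unclass(geno)[keep, , drop = FALSE], map)
  }

  probs <- conditional_probabilities(geno, map, step = config$step,
                                     expansion = config$expansion)
  sex_cov <- NULL
  if (is.null(config$sex_filter) && config$sex_covar != "none" &&
      length(unique(phen$sex)) > 1) {
    sex_cov <- covariate_spec("sex", as.numeric(phen$sex == "M"),
                              config$sex_covar)
  }

  scans <- list(); thresholds <- list(); fits <- list(); intervals <- list()
  report <- NULL
  for (tr in config$traits) {
    y <- phen[[tr]]
    model <- if (tr == "INC") "binary" else "hk"
    sc <- if (model == "binary") {
      scan_binary(y, probs, sex_cov, trait_name = tr)
    } else {
      scan_hk(y, probs, sex_cov, trait_name = tr)
    }
    scans[[tr]] <- sc
    thr <- if (config$threshold_method == "family_residual") {
      family_residual_threshold(y, probs, phen$family, sex_cov, trait_name = tr)
    } else {
      fallback_threshold()
    }
    thresholds[[tr]] <- thr
    eff_thr <- max(thr$threshold, config$threshold_floor)
    peaks <- find_qtl_peaks(sc, eff_thr, drop = config$drop,
                            max_peaks = config$max_peaks)
    intervals[[tr]] <- peaks
    prob_pct <- rep(NA_real_, length(peaks))
    if (length(peaks)) {
      prob_pct <- localization_probability(
        y, probs, peaks, eff_thr, n_boot = config$n_boot,
        seed = derive_seed(config$seed, paste0("boot_", tr)),
        model = model, cov = sex_cov)
    }
    fit <- NULL
    if (length(peaks) == 2) {
      fit <- tryCatch(
        fit_two_qtl(y, probs, peaks[[1]]$peak_pos, peaks[[2]]$peak_pos,
                    cov = sex_cov, model = model),
        error = function(e) NULL)
    }
    fits[[tr]] <- fit
    if (length(peaks)) {
      rows <- do.call(rbind, lapply(seq_along(peaks), function(k) {
        data.frame(trait = tr, threshold = round(thr$threshold, 2),
                   qtl = k,
                   peak_marker = nearest_marker(map, peaks[[k]]$peak_pos),
                   peak_pos_mb = peaks[[k]]$peak_pos,
                   peak_lod = round(peaks[[k]]$peak_lod, 2),
                   si_lower = peaks[[k]]$lower, si_upper = peaks[[k]]$upper,
                   prob_pct = round(prob_pct[k], 1),
                   fit_p = if (!is.null(fit)) signif(fit$p_value[k], 3) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
      report <- rbind(report, rows)
    } else {
      report <- rbind(report, data.frame(
        trait = tr, threshold = round(thr$threshold, 2), qtl = NA_integer_,
        peak_marker = NA_character_, peak_pos_mb = NA_real_,
        peak_lod = round(max(sc$lod), 2), si_lower = NA_real_,
        si_upper = NA_real_, prob_pct = NA_real_, fit_p = NA_real_,
        stringsAsFactors = FALSE))
    }
  }

  rownames(report) <- NULL
  peak_markers <- unique(stats::na.omit(report$peak_marker))
  m_tests <- config$m_tests %||% max(1, length(peak_markers) * 6)
  effects <- lapply(peak_markers, function(mk) {
    tryCatch(stratify_and_test(mk, geno, phen, alpha = config$alpha,
                               m_tests = m_tests),
             error = function(e) NULL)
  })
  names(effects) <- peak_markers

  out <- list(report = report, scans = scans, thresholds = thresholds,
              intervals = intervals, fits = fits, effects = effects,
              map = map, genotypes = geno, phenotypes = phen,
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(config$out_dir, "qtl_report.csv"),
                     row.names = FALSE, quote = FALSE)
    for (tr in names(scans)) {
      write_scan(scans[[tr]], file.path(config$out_dir,
                                        paste0("scan_", tr, ".csv")))
    }
    writeLines(c(sprintf("ailqtl %s", as.character(utils::packageVersion("ailqtl"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("n individuals: %d", nrow(phen)),
                 sprintf("traits: %s", paste(config$traits, collapse = ", ")),
                 sprintf("threshold method: %s", config$threshold_method),
                 sprintf("expansion: %g", config$expansion)),
               file.path(config$out_dir, "run_log.txt"))
  }
  out
}
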