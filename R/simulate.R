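# Synthetic advanced intercross line (AIL) cohorts.
#
# The simulator reproduces the statistical structure the downstream
# analysis assumes: per-meiosis recombination under the Haldane map
# function accumulated over generations, a limited number of breeding
# couples per generation (hence genetic drift and sibship/family
# structure), genotype-class penetrance for the binary incidence trait,
# and genotype-class means plus family and sex effects for quantitative
# traits.

#' Specify a QTL for simulation
#'
#' A QTL contributes a genotype-class mean to the latent quantitative
#' severity (`effect_*`, phenotype units) and, optionally, a per-locus
#' penetrance for the binary incidence trait (`pen_*`, probabilities).
#' Across loci, penetrances are combined on the log-odds scale relative to
#' the configured baseline penetrance, so a single-QTL architecture
#' reproduces its stated penetrances exactly.
#'
#' @param position QTL position in Mb; must lie within the map span.
#' @param mode Allelic-effect architecture: `"additive"`, `"dominant_A"`,
#'   `"dominant_B"` (the named allele's effect is dominant) or
#'   `"heterosis"` (heterozygote outside both homozygote means).
#' @param effect_AA,effect_AB,effect_BB Genotype-class means on the latent
#'   quantitative severity scale.
#' @param pen_AA,pen_AB,pen_BB Optional genotype-class penetrances in
#'   \[0, 1\] for the binary trait.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(position, mode,
                     effect_AA = 0, effect_AB = 0, effect_BB = 0,
                     pen_AA = NULL, pen_AB = NULL, pen_BB = NULL) {
  mode <- match.arg(mode, c("additive", "dominant_A", "dominant_B", "heterosis"))
  eff <- c(AA = effect_AA, AB = effect_AB, BB = effect_BB)
  if (any(!is.finite(eff))) stop("QTL effects must be finite")
  if (mode == "heterosis" &&
      effect_AB > min(effect_AA, effect_BB) &&
      effect_AB < max(effect_AA, effect_BB)) {
    stop("heterosis mode requires effect_AB strictly outside the homozygote range")
  }
  pen <- NULL
  if (!is.null(pen_AA) || !is.null(pen_AB) || !is.null(pen_BB)) {
    pen <- c(AA = pen_AA %||% NA_real_, AB = pen_AB %||% NA_real_,
             BB = pen_BB %||% NA_real_)
    if (any(is.na(pen))) stop("give all three penetrances or none")
    if (any(pen < 0 | pen > 1)) stop("penetrances must lie in [0, 1]")
  }
  structure(list(position = as.numeric(position), mode = mode,
                 effect = eff, penetrance = pen),
            class = "qtl_spec")
}

#' Configure an AIL simulation
#'
#' @param map A [genetic_map()] of the markers to genotype; cM positions
#'   are derived at `cm_per_mb` if the map lacks a `pos_cm` column.
#' @param qtl_specs List of [qtl_spec()] objects (possibly empty).
#' @param n_generations Number of intercross generations; 2 corresponds to
#'   an F2, 10 to a G10 AIL.
#' @param n_couples Breeding couples maintained per generation.
#' @param n_offspring Offspring per couple in the final (phenotyped)
#'   generation.
#' @param family_effect_sd SD of the shared final-generation sibship effect
#'   on quantitative traits (phenotype units).
#' @param residual_sd SD of the individual Gaussian residual (> 0).
#' @param trait_mean Baseline latent severity among affected individuals.
#' @param sex_effect Additive male effect on the latent severity
#'   (phenotype units; females are the reference).
#' @param base_penetrance Baseline incidence penetrance; per-QTL
#'   penetrances are log-odds offsets from this value.
#' @param sex_effect_inc Log-odds added to male incidence (negative =
#'   males less susceptible).
#' @param geno_missing Probability that a marker genotype is missing.
#' @param cm_per_mb Mb-to-cM conversion rate used when simulating
#'   recombination.
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical output tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(map, qtl_specs = list(),
                       n_generations = 10, n_couples = 50, n_offspring = 16,
                       family_effect_sd = 0.25, residual_sd = 0.8,
                       trait_mean = 2.0, sex_effect = 0,
                       base_penetrance = 0.3, sex_effect_inc = 0,
                       geno_missing = 0, cm_per_mb = 1, seed = 1) {
  map <- as_genetic_map(map)
  if (nrow(map) < 2) stop("map must have at least 2 markers")
  if (is.null(map$pos_cm)) map <- derive_cm_positions(map, cm_per_mb)
  if (n_generations < 2) stop("n_generations must be >= 2 (2 = F2)")
  if (n_couples < 1) stop("n_couples must be >= 1")
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  if (family_effect_sd < 0) stop("family_effect_sd must be >= 0")
  if (residual_sd <= 0) stop("residual_sd must be > 0")
  if (base_penetrance < 0 || base_penetrance > 1) {
    stop("base_penetrance must lie in [0, 1]")
  }
  if (geno_missing < 0 || geno_missing >= 1) stop("geno_missing must be in [0, 1)")
  if (!is.finite(sex_effect) || !is.finite(trait_mean)) {
    stop("trait effects must be finite")
  }
  if (inherits(qtl_specs, "qtl_spec")) qtl_specs <- list(qtl_specs)
  lo <- min(map$pos_mb); hi <- max(map$pos_mb)
  for (q in qtl_specs) {
    if (!inherits(q, "qtl_spec")) stop("qtl_specs must be qtl_spec objects")
    if (q$position < lo || q$position > hi) {
      stop(sprintf("QTL at %.2f Mb lies outside the map span [%.2f, %.2f]",
                   q$position, lo, hi))
    }
  }
  structure(list(map = map, qtl_specs = qtl_specs,
                 n_generations = as.integer(n_generations),
                 n_couples = as.integer(n_couples),
                 n_offspring = as.integer(n_offspring),
                 family_effect_sd = family_effect_sd,
                 residual_sd = residual_sd, trait_mean = trait_mean,
                 sex_effect = sex_effect,
                 base_penetrance = base_penetrance,
                 sex_effect_inc = sex_effect_inc,
                 geno_missing = geno_missing, cm_per_mb = cm_per_mb,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One gamete per row of (h1, h2): haplotype matrices of 0 (A) / 1 (B).
# r[j] is the recombination fraction between locus j and j+1.
make_gametes <- function(h1, h2, r) {
  n <- nrow(h1); L <- ncol(h1)
  strand <- matrix(0L, n, L)
  strand[, 1] <- sample(c(0L, 1L), n, replace = TRUE)
  if (L > 1) {
    for (j in 2:L) {
      sw <- stats::runif(n) < r[j - 1]
      strand[, j] <- ifelse(sw, 1L - strand[, j - 1], strand[, j - 1])
    }
  }
  ifelse(strand == 0L, h1, h2)
}

# Balanced random sex assignment (guarantees enough of each sex to pair).
assign_sexes <- function(n) {
  sample(rep_len(c("F", "M"), n))
}

# Pair males and females from one generation into n_couples couples,
# avoiding full-sib matings where possible.
pair_couples <- function(sex, family, n_couples) {
  males <- sample(which(sex == "M"))
  females <- sample(which(sex == "F"))
  if (length(males) < n_couples || length(females) < n_couples) {
    stop("not enough individuals of each sex to form couples")
  }
  sires <- integer(n_couples); dams <- integer(n_couples)
  used <- rep(FALSE, length(females))
  for (i in seq_len(n_couples)) {
    m <- males[i]
    ok <- which(!used & family[females] != family[m])
    pick <- if (length(ok)) ok[1] else which(!used)[1]
    used[pick] <- TRUE
    sires[i] <- m; dams[i] <- females[pick]
  }
  list(sire = sires, dam = dams)
}

#' Simulate an advanced intercross line
#'
#' Starting from an F1 between two fully homozygous founder strains
#' (A = DA-like, B = PVG-like), the population is bred for
#' `n_generations` with `n_couples` random (sib-avoiding) breeding couples
#' per generation.  Meioses recombine under the Haldane map function on
#' the cM scale.  The final generation is phenotyped: incidence from
#' genotype-class penetrance, quantitative traits from genotype-class
#' means plus family, sex and Gaussian residual effects, with
#' onset/duration/cumulative score generated only for affected animals.
#'
#' @param config A [sim_config()].
#' @return List with `pedigree` (all simulated individuals), `genotypes`
#'   (final generation, [genotype_matrix()]), `phenotypes` (final
#'   generation, [phenotype_table()] with the continuous latent severity
#'   kept in an extra `SEV` column) and `map` (with cM positions).
#' @export
simulate_ail <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- config$map
  qtl_pos_cm <- vapply(config$qtl_specs, function(q) q$position, 0) *
    config$cm_per_mb
  loci_cm <- sort(unique(c(map$pos_cm, qtl_pos_cm)))
  r <- haldane(diff(loci_cm))
  marker_cols <- match(map$pos_cm, loci_cm)
  qtl_cols <- match(qtl_pos_cm, loci_cm)
  L <- length(loci_cm)

  n_f1 <- 2L * config$n_couples
  h1 <- matrix(0L, n_f1, L)   # DA haplotype
  h2 <- matrix(1L, n_f1, L)   # PVG haplotype
  sex <- assign_sexes(n_f1)
  family <- rep(seq_len(config$n_couples), each = 2)[seq_len(n_f1)]
  ids <- sprintf("G1_%04d", seq_len(n_f1))
  ped <- data.frame(id = ids, generation = 1L, sire = NA_character_,
                    dam = NA_character_, sex = sex,
                    family = sprintf("G1F%03d", family),
                    stringsAsFactors = FALSE)

  for (g in 2:config$n_generations) {
    couples <- pair_couples(sex, family, config$n_couples)
    final <- g == config$n_generations
    k <- if (final) config$n_offspring else 4L
    sire_idx <- rep(couples$sire, each = k)
    dam_idx <- rep(couples$dam, each = k)
    n_off <- length(sire_idx)
    oh1 <- make_gametes(h1[sire_idx, , drop = FALSE],
                        h2[sire_idx, , drop = FALSE], r)
    oh2 <- make_gametes(h1[dam_idx, , drop = FALSE],
                        h2[dam_idx, , drop = FALSE], r)
    osex <- assign_sexes(n_off)
    ofam <- rep(seq_len(config$n_couples), each = k)
    oid <- sprintf("G%d_%04d", g, seq_len(n_off))
    ped <- rbind(ped, data.frame(
      id = oid, generation = g, sire = ids[sire_idx], dam = ids[dam_idx],
      sex = osex, family = sprintf("G%dF%03d", g, ofam),
      stringsAsFactors = FALSE))
    h1 <- oh1; h2 <- oh2; sex <- osex; family <- ofam; ids <- oid
  }

  geno_code <- h1 + h2  # 0 = AA, 1 = AB, 2 = BB per locus
  n <- nrow(geno_code)

  # --- binary incidence from penetrance --------------------------------
  p0 <- config$base_penetrance
  eta <- rep(if (p0 > 0 && p0 < 1) logit(p0) else stats::qlogis(0.5), n)
  for (i in seq_along(config$qtl_specs)) {
    q <- config$qtl_specs[[i]]
    if (is.null(q$penetrance)) next
    pen <- pmin(pmax(q$penetrance, 1e-12), 1 - 1e-12)
    eta <- eta + logit(pen)[geno_code[, qtl_cols[i]] + 1L] - logit(max(min(p0, 1 - 1e-12), 1e-12))
  }
  eta <- eta + ifelse(sex == "M", config$sex_effect_inc, 0)
  p_inc <- if (p0 == 0) rep(0, n) else if (p0 == 1) rep(1, n) else inv_logit(eta)
  inc <- stats::rbinom(n, 1, p_inc)

  # --- latent quantitative severity ------------------------------------
  fam_eff <- stats::rnorm(config$n_couples, 0, config$family_effect_sd)
  sev <- config$trait_mean + fam_eff[family] +
    ifelse(sex == "M", config$sex_effect, 0) +
    stats::rnorm(n, 0, config$residual_sd)
  for (i in seq_along(config$qtl_specs)) {
    q <- config$qtl_specs[[i]]
    sev <- sev + q$effect[geno_code[, qtl_cols[i]] + 1L]
  }

  # EAE trait panel; disease-course traits exist only for affected animals
  aff <- inc == 1
  MAX <- ifelse(aff, pmin(4, pmax(0.5, round(sev * 2) / 2)), 0)
  ONS <- rep(NA_real_, n)
  ONS[aff] <- round(pmin(34, pmax(10, stats::rnorm(sum(aff), 27 - 1.8 * sev[aff], 2.5))))
  DUR <- rep(0, n)
  DUR[aff] <- pmin(35 - ONS[aff] + 1,
                   pmax(1, round(2.2 * sev[aff] + stats::rnorm(sum(aff), 0, 1.5))))
  CUM <- rep(0, n)
  CUM[aff] <- pmax(0.5, round(0.55 * MAX[aff] * DUR[aff] +
                                stats::rnorm(sum(aff), 0, 1.5), 1))
  WL <- numeric(n)
  WL[aff] <- pmax(0, round(3 + 3 * sev[aff] + stats::rnorm(sum(aff), 0, 2.5), 1))
  WL[!aff] <- pmax(0, round(stats::rnorm(sum(!aff), 0.8, 0.8), 1))

  gm <- matrix(GENO_CODES[geno_code[, marker_cols, drop = FALSE] + 1L],
               nrow = n, dimnames = list(ids, map$marker))
  if (config$geno_missing > 0) {
    drop <- matrix(stats::runif(length(gm)) < config$geno_missing, nrow = n)
    gm[drop] <- NA_character_
  }

  phen <- phenotype_table(data.frame(
    id = ids, sex = sex,
    family = sprintf("G%dF%03d", config$n_generations, family),
    INC = inc, ONS = ONS, MAX = MAX, DUR = DUR, CUM = CUM, WL = WL,
    SEV = sev, stringsAsFactors = FALSE))

  list(pedigree = ped, genotypes = genotype_matrix(gm, map),
       phenotypes = phen, map = map)
}

#' Default two-QTL AIL fixture
#'
#' A desk-scale G10 AIL cohort modelled on a rat chromosome-17 EAE region:
#' 20 microsatellite markers over 13.9-81.6 Mb (including an image of the
#' 33.3-42.7 Mb non-polymorphic stretch as a long inter-marker gap), 50
#' breeding couples per generation, and two linked QTLs -- a dominant,
#' transgressive susceptibility locus at 47.3 Mb (protective A/A homozygote)
#' and a heterotic locus at 62.0 Mb whose heterozygote penetrance is about
#' 1.6 times the homozygote penetrance.  Overall incidence is calibrated to
#' about 29% across both sexes, with males less susceptible.
#'
#' @param seed Integer seed.
#' @param n_offspring Offspring per couple in the phenotyped generation
#'   (default 17, about 850 animals of which roughly half are female).
#' @return As [simulate_ail()]: list with `pedigree`, `genotypes`,
#'   `phenotypes`, `map`.
#' @export
make_eae23_fixture <- function(seed = 1, n_offspring = 17) {
  cfg <- eae23_config(seed = seed, n_offspring = n_offspring)
  simulate_ail(cfg)
}

#' @rdname make_eae23_fixture
#' @export
eae23_map <- function() {
  pos <- c(13.9, 17.5, 21.0, 24.5, 27.6, 30.5, 33.3, 42.7, 45.0, 47.3,
           50.5, 53.8, 57.0, 59.5, 61.8, 62.3, 66.0, 70.5, 75.8, 81.6)
  known <- c("27.6" = "D17Rat8", "33.3" = "D17Rat12", "42.7" = "D17Got49",
             "47.3" = "D17Got45", "61.8" = "D17Got120", "62.3" = "D17Got70",
             "75.8" = "D17Rat37")
  nm <- ifelse(!is.na(known[as.character(pos)]), known[as.character(pos)],
               sprintf("D17Sim%02d", seq_along(pos)))
  genetic_map(unname(nm), "17", pos)
}

#' @rdname make_eae23_fixture
#' @export
eae23_config <- function(seed = 1, n_offspring = 17) {
  qtl_a <- qtl_spec(47.3, "dominant_B",
                    effect_AA = -0.30, effect_AB = 0.15, effect_BB = 0.15,
                    pen_AA = 0.125, pen_AB = 0.321, pen_BB = 0.321)
  qtl_b <- qtl_spec(62.0, "heterosis",
                    effect_AA = -0.15, effect_AB = 0.30, effect_BB = -0.15,
                    pen_AA = 0.321, pen_AB = 0.500, pen_BB = 0.321)
  sim_config(eae23_map(), list(qtl_a, qtl_b),
             n_generations = 10, n_couples = 50, n_offspring = n_offspring,
             family_effect_sd = 0.25, residual_sd = 0.8,
             trait_mean = 2.0, sex_effect = -0.2,
             base_penetrance = 0.321, sex_effect_inc = -0.65,
             geno_missing = 0, cm_per_mb = 1, seed = seed)
}
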