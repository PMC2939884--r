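---
title: "Mapping linked disease loci in an advanced intercross line: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping linked disease loci in an advanced intercross line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailqtl)
```

## The problem

An advanced intercross line (AIL) is produced by crossing two inbred
strains and then intercrossing the population for many generations —
here ten (G10) — with a limited number of breeding couples.  Each extra
generation adds a round of meioses, so recombination accumulates and a
quantitative trait locus (QTL) that an F2 would localize to tens of
megabases can be resolved to a few megabases.  The price is structure:
the cohort is a collection of sibships ("families") whose members share
genotypes and environment, drift skews allele frequencies when only ~50
couples breed each generation, and standard permutation thresholds are
no longer valid because individuals are not exchangeable across
families.

`ailqtl` implements a complete analysis for this design, motivated by
rat experimental autoimmune encephalomyelitis (EAE) genetics: a
chromosome-17 region in a (DA x PVG.1AV1) G10 AIL harbouring two linked
loci — one at 47.3 Mb where alleles from the EAE-resistant strain
promote disease dominantly (transgressive segregation), one at 62.0 Mb
where heterozygotes are more susceptible than either homozygote
(heterosis).  Because the original cohort's individual-level data are
not deposited, the package ships a simulator that reproduces the
statistical structure of such a cohort, and every procedure is tested
against it.

## The scan models

Genotype information enters through conditional genotype-class
probabilities.  At scan position $p$, an individual's probability of
being `AA`, `AB` or `BB` is computed from the nearest informative
flanking markers under a two-locus Markov model per chromosome, with
Haldane recombination fractions $r = (1 - e^{-2d/100})/2$ on the cM
scale.  Positions beyond the terminal typed markers condition on the
single nearest marker; an individual with no typed marker receives the
intercross prior $(1/4, 1/2, 1/4)$ and a warning.

Recombination accumulated over the intercross generations is modelled
by a map-expansion factor (default $t/2$ for generation $t$, i.e. 5 for
G10).  The factor multiplies cM *distances* before the Haldane
transform rather than the recombination fractions themselves: distance
scaling preserves the composition property
$T(r_{L\to p})\,T(r_{p\to R}) = T(r_{L\to R})$ that the
flanking-marker conditioning relies on, and agrees with fraction
scaling to first order in $r$.  With fully typed markers and a
markers-only grid (the default), the expansion factor does not affect
the scan at all; it matters for missing-genotype imputation and
pseudo-position grids.

For a quantitative trait $y$, Haley-Knott regression fits at each
position

$$ y_i = \mu + \beta_a a_i + \beta_d d_i + \gamma' c_i + e_i, $$

with additive dosage $a_i = P(BB) - P(AA) \in [-1, 1]$, dominance
$d_i = P(AB)$, and optional covariates $c_i$ (sex, additively or with
QTL-by-covariate interaction).  The LOD score is
$\tfrac{n}{2}\log_{10}(RSS_0/RSS_1)$ against the covariate-only null.
For the binary incidence trait the same regressors enter a logistic
model and $\mathrm{LOD} = (\ell_1 - \ell_0)/\ln 10$; complete
separation is caught and refitted with a small ridge penalty
($\lambda = 10^{-4}$, flagged in a warning).  Traits that are undefined
for part of the cohort (day of onset for unaffected animals) are
dropped, not imputed.  At least 8 non-missing values and positive trait
variance are required.

## Thresholds: family residuals, not permutation

Permutation of the trait across the cohort is invalid here: families
share both genotypes and environment, so the permutation null destroys
real structure and under- or over-states the significance threshold
depending on the trait.  The pipeline instead computes, per trait, the
maximum LOD of a rescan of *within-family residuals*
($y_i - \bar{y}_{\mathrm{family}(i)}$), and reports a QTL only where
the original scan exceeds this threshold (a fixed 3.4 cut-off from
classical simulation studies is available as
`fallback_threshold()`, and `run_config(threshold_floor=)` lets the
two be combined).  Residuals of the 0/1 incidence coding are
continuous, so the residual rescan always uses the Haley-Knott
machinery.

Two properties of this procedure are worth knowing.  First, its
threshold agrees with a within-family permutation null: on simulated
no-QTL cohorts with family effects, the threshold falls inside the
central 95% band of the max-LOD distribution obtained by permuting the
trait within families (this is checked in the test suite).  Second, it
is *anti-conservative* relative to the unconditional null maximum: sibs
share marker genotypes, so part of a raw null scan's max LOD comes from
chance between-family association, and family-mean centering removes
exactly that component.  On no-QTL cohorts the threshold exceeds the
realized raw-scan maximum only a minority of the time.  This is a
property of the procedure itself, not of the implementation, and it is
the reason the fixed 3.4 cut-off remains useful alongside it.

## Support intervals and multi-QTL calling

A QTL's support interval is bounded by the closest flanking markers
whose LOD falls more than 1.5 below the peak (the bound *is* that
marker's position; a side with no such marker is clipped at the region
end; ties at the peak break toward the smaller position).  The 1.5-LOD
interval is conventionally treated as approximately a 95% confidence
interval for QTL location in intercrosses; `interval_coverage()`
re-derives this by simulation (300 F2 replicates, n = 400, markers
every 5 cM, one additive QTL at 52 cM explaining ~10% of variance) and
observes coverage in the high 90s — the closest-marker-outside rule
rounds intervals outward, so coverage sits at or above the nominal
95%.

Calling two linked QTLs from one scan requires a distinctness rule the
underlying method does not define.  `find_qtl_peaks()` accepts
candidate peaks in decreasing LOD order; a supra-threshold candidate is
accepted as a distinct QTL only if it lies outside the support interval
of every already-accepted peak.  This mirrors how closely linked loci
are argued apart in practice — a second peak inside another QTL's
confidence interval is not separable evidence — and each accepted
peak's own interval is then computed within its basin, delimited by the
valley minima between accepted peaks.  A valley-depth rule (requiring
the curve to dip 1.5 below the smaller peak) was considered and
rejected: it refuses to call a genuine second locus whose peak is
modest even when it sits far outside the first locus's interval.

Two follow-ups quantify the separation.  `fit_two_qtl()` fits both loci
jointly (additive + dominance terms each) and drops each in turn — an F
test for Haley-Knott, a 2-df likelihood-ratio test for the binary model
— declaring independent effects at the usual 0.05/0.01 tiers.
`localization_probability()` resamples individuals with replacement
(the "simulated pedigrees" bootstrap), rescans each replicate with a
single-QTL model so that linked loci must compete for the peak, and
reports the percentage of replicates whose supra-threshold maximum
falls inside each interval.  Sub-threshold replicates stay in the
denominator by default — the probabilities for competing linked QTLs
then sum below 100%, matching how such tables are reported — and
`count_subthreshold = FALSE` switches to the conditional reading, since
the convention is ambiguous in the field.

## Allelic effects and classification

At a peak marker the cohort is stratified by genotype class and tested
nonparametrically (EAE scores are heavily tied): Kruskal-Wallis across
classes per quantitative trait, pairwise Mann-Whitney contrasts, and
Fisher's exact test for incidence, with Bonferroni adjustment
(`m_tests` defaults in the pipeline to peak-markers x phenotypes, the
most conservative reading).  The allelic architecture is classified
from the three contrast patterns — heterozygote vs each homozygote and
homozygote vs homozygote.  Contrast significance pools evidence across
the clinical panel (the minimum adjusted p per contrast), with each
trait oriented so that larger means more severe (day of onset is
flipped); this matches how allelic effects are judged in practice,
where a locus's architecture is claimed across all phenotypes rather
than from a single one, and it gives the classifier usable power at
realistic effect sizes.  `heterosis` requires the heterozygote to
differ from both homozygotes in the same severity direction;
`dominant_A`/`dominant_B` require the heterozygote to track one
homozygote while the homozygotes differ; `additive` covers the
remaining significant homozygote contrasts.  The transgressive flag is
set when the resistant-strain allele's homozygote is the more severely
affected class.

`predict_congenic()` performs the genotype-matched congenic
prediction: AIL individuals carrying the two-locus genotype
combinations that congenic strains capture are selected, summarized,
and compared against the background-strain combination (Fisher for
incidence, Mann-Whitney otherwise).  Note one instructive consequence
of the simulator's architecture: with a dominant promoting locus and a
heterotic locus, the doubly heterozygous combination is necessarily the
*most* severe class, not intermediate — the original congenic
experiments observed an intermediate heterozygote phenotype, which is
precisely why the heterosis effect could not be confirmed in congenics.

## The ΔΔCt module

Relative expression from qPCR Ct tables uses the standard
$2^{-\Delta\Delta C_t}$ method with amplification efficiency fixed at 2
(the design assumes target and reference efficiencies are
approximately equivalent): $\Delta C_{t,i} =
C_t^{target} - C_t^{ref}$, centred on the mean $\Delta C_t$ of a
calibrator set (all samples by default, or one named group), so the
geometric mean of RQ over the calibrator set is exactly 1.  Decreasing
a sample's target Ct by one cycle exactly doubles its RQ, and adding a
constant to both target and reference Ct of every sample leaves RQ
unchanged; both identities are tested.

## The simulator

`simulate_ail()` breeds an F1 between fully homozygous founders through
`n_generations` with `n_couples` random couples per generation
(sib-avoiding pairing; the original breeding protocol specifies only
couple counts).  Meioses recombine under Haldane on the cM scale
(physical Mb positions are converted at a configurable uniform rate,
default 1 cM/Mb, since the original analysis mapped on physical
positions and never states a genetic scale).  Intermediate generations
produce 4 offspring per couple with balanced sexes; the final
generation produces `n_offspring` per couple and is phenotyped, with
the couple defining the family (sibship) id.

The binary incidence trait is drawn from genotype-class penetrance (not
a liability threshold — incidence is reported per genotype class, so
penetrance is the directly parameterized quantity).  With several loci,
per-locus penetrances combine on the log-odds scale relative to the
baseline penetrance; a single-locus architecture reproduces its stated
penetrances exactly.  Quantitative traits derive from a latent severity
(genotype-class means + family effect + sex effect + Gaussian noise,
kept in the output as `SEV`); the EAE panel is generated conditionally
— onset, duration and cumulative score exist only for affected animals,
unaffected animals score zero, duration respects the 35-day observation
window, and weight loss is floored at zero (the minimum over the weight
series includes day 0, so weight-gaining animals get 0 rather than a
negative loss).

`make_eae23_fixture()` is the default cohort: 20 microsatellite markers
spanning 13.9–81.6 Mb (67.7 Mb) including a long marker gap standing in
for a non-polymorphic stretch at 33.3–42.7 Mb, 10 generations, 50
couples, 17 offspring per final couple (~850 animals, ~425 females —
litter/selection details of the original cohort are under-described, so
equal sibships are used).  The penetrance parameters (baseline 0.321;
protective `AA` at the 47.3 Mb locus 0.125; heterozygote at the 62.0 Mb
locus 0.500; male log-odds −0.65) were solved analytically so that the
female cohort shows ~43% incidence in 62-Mb heterozygotes vs ~27% in
homozygotes (a 1.6-fold heterosis ratio) and the full cohort ~29%
incidence.  What the simulator does *not* model: any immune mechanism
or disease-course dynamics, X-linked or mitochondrial inheritance,
genotyping error, and litter-size variation — so passing tests show the
statistical machinery behaves correctly under the assumed structure,
not that the biology is captured.

## Numerical choices and problem sizes

Dosage coding is `AA` = −1, `BB` = +1, dominance = P(AB).  Probability
triples normalize to 1 within 1e−9.  A perfect Haley-Knott fit (RSS
below 1e−12) caps the LOD with a warning.  Logistic separation uses
ridge IRLS with λ = 1e−4 on non-intercept coefficients.  Collinear
dosages in the two-locus fit (|r| > 0.999) are an error advising wider
spacing.  Interval containment is closed on both bounds.  All
randomness flows through explicit seeds; a pipeline run derives one
seed per stage from the master seed so stages can be re-run
independently, and identical configurations are byte-identical.

The test suite and the coverage experiment use deliberately desk-scale
sizes chosen as reasonable Monte-Carlo compromises: 300 replicates for
interval coverage, 100 fixture seeds for the two-locus recovery and
heterosis-classification rates, 400 replicates for drop-term type-I
calibration, 500 permutations for null-scan calibration, and 150
replicates per couple-count for the drift monotonicity check.
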