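# Internal helpers shared across modules.

GENO_CODES <- c("AA", "AB", "BB")

#' Haldane map function
#'
#' Convert a genetic distance in centiMorgans to a recombination fraction
#' under the Haldane (no-interference) map function,
#' \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d_cm Genetic distance(s) in cM (non-negative).
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
haldane <- function(d_cm) {
  stopifnot(all(d_cm >= 0))
  0.5 * (1 - exp(-2 * d_cm / 100))
}

# Expansion-scaled recombination fraction between two cM positions.
# Scaling is applied to the distance (not to r itself) so that transition
# matrices compose along the chromosome.
expanded_rf <- function(d_cm, expansion = 1) {
  haldane(d_cm * expansion)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Run code under a temporary RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a master seed so pipeline stages are
# independently re-runnable.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
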