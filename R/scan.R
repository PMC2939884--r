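# Single-QTL genome-region scans.
#
# Haley-Knott regression for quantitative traits: at each position the
# trait is regressed on the additive dosage a = P(BB) - P(AA) in [-1, 1]
# and the dominance term d = P(AB), plus covariates, and
# LOD = (n/2) log10(RSS0 / RSS1) against the covariate-only null.
# A logistic model plays the same role for the binary incidence trait,
# with LOD = (l1 - l0) / ln 10 from maximized log-likelihoods.

#' Specify a scan covariate
#'
#' @param name Covariate name (used in scan provenance).
#' @param values Numeric vector or factor, one value per grid individual.
#' @param role `"additive"` (main effect only) or `"interactive"` (main
#'   effect plus QTL-by-covariate interaction; interactive models always
#'   contain the additive terms).
#' @return A `covariate_spec`.
#' @export
covariate_spec <- function(name, values, role = c("additive", "interactive")) {
  role <- match.arg(role)
  if (is.character(values)) values <- factor(values)
  if (is.factor(values)) {
    cols <- stats::model.matrix(~values)[, -1, drop = FALSE]
    colnames(cols) <- paste0(name, levels(values)[-1])
    values <- cols
  } else {
    values <- matrix(as.numeric(values), dimnames = list(NULL, name))
  }
  structure(list(name = name, values = values, role = role),
            class = "covariate_spec")
}

covar_tag <- function(cov) {
  if (is.null(cov)) "none" else paste0(cov$name, ":", cov$role)
}

# Extract dosage regressors at grid position p for the given rows.
dosage_at <- function(probs, p, rows) {
  a <- probs[rows, p, 3] - probs[rows, p, 1]
  d <- probs[rows, p, 2]
  cbind(a = a, d = d)
}

rss_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Haley-Knott regression scan
#'
#' @param trait Numeric trait values, one per grid individual (`NA`s are
#'   dropped; at least 8 non-missing values required).
#' @param probs A `genoprob_grid` from [conditional_probabilities()].
#' @param cov Optional [covariate_spec()].
#' @param trait_name Trait label recorded in the result.
#' @return A [scan_result()] with model tag `"haley_knott"`.
#' @export
scan_hk <- function(trait, probs, cov = NULL, trait_name = "trait") {
  stopifnot(inherits(probs, "genoprob_grid"))
  n_all <- dim(probs)[1]
  if (length(trait) != n_all) {
    stop("trait length must match the probability grid (", n_all, ")")
  }
  rows <- which(is.finite(trait))
  if (length(rows) < 8) stop("need >= 8 non-missing trait values")
  y <- trait[rows]
  if (stats::var(y) == 0) stop("trait has zero variance")
  C <- if (is.null(cov)) NULL else cov$values[rows, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  rss0 <- rss_fit(X0, y)
  pos <- attr(probs, "pos_mb")
  n <- length(y)
  capped <- FALSE
  lod <- vapply(seq_along(pos), function(p) {
    Q <- dosage_at(probs, p, rows)
    X1 <- X0
    X1 <- cbind(X1, Q)
    if (!is.null(cov) && cov$role == "interactive") {
      for (j in seq_len(ncol(C))) {
        X1 <- cbind(X1, Q * C[, j])
      }
    }
    rss1 <- rss_fit(X1, y)
    if (rss1 < 1e-12) {
      capped <<- TRUE
      rss1 <- 1e-12
    }
    (n / 2) * log10(rss0 / rss1)
  }, 0)
  if (capped) warning("perfect fit at one or more positions; LOD capped")
  scan_result(pos, pmax(0, lod), trait = trait_name, model = "haley_knott",
              covar = covar_tag(cov), n = n)
}

binom_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Ridge-penalised logistic IRLS used when ordinary ML separates.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100) {
  beta <- rep(0, ncol(X))
  pen <- rep(lambda, ncol(X)); pen[1] <- 0  # intercept unpenalised
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(pen, ncol(X))
    g <- crossprod(X, y - mu) - pen * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  list(beta = beta, loglik = binom_loglik(y, inv_logit(drop(X %*% beta))))
}

logistic_loglik <- function(X, y, ridge_lambda = 1e-4) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || sep || max(abs(fit$coefficients), na.rm = TRUE) > 15) {
    rf <- ridge_logistic(X, y, ridge_lambda)
    return(list(loglik = rf$loglik, separated = TRUE))
  }
  list(loglik = binom_loglik(y, fit$fitted.values), separated = FALSE)
}

#' Binary-trait logistic scan
#'
#' @param inc 0/1 incidence values, one per grid individual; both classes
#'   must be present.
#' @param probs A `genoprob_grid`.
#' @param cov Optional [covariate_spec()].
#' @param trait_name Trait label (default `"INC"`).
#' @param ridge_lambda Ridge penalty applied when complete separation is
#'   detected (flagged in a warning).
#' @return A [scan_result()] with model tag `"binary"`.
#' @export
scan_binary <- function(inc, probs, cov = NULL, trait_name = "INC",
                        ridge_lambda = 1e-4) {
  stopifnot(inherits(probs, "genoprob_grid"))
  n_all <- dim(probs)[1]
  if (length(inc) != n_all) {
    stop("trait length must match the probability grid (", n_all, ")")
  }
  rows <- which(is.finite(inc))
  y <- inc[rows]
  if (!all(y %in% c(0, 1))) stop("INC must be 0/1")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  C <- if (is.null(cov)) NULL else cov$values[rows, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  f0 <- logistic_loglik(X0, y, ridge_lambda)
  pos <- attr(probs, "pos_mb")
  any_sep <- f0$separated
  lod <- vapply(seq_along(pos), function(p) {
    Q <- dosage_at(probs, p, rows)
    X1 <- cbind(X0, Q)
    if (!is.null(cov) && cov$role == "interactive") {
      for (j in seq_len(ncol(C))) X1 <- cbind(X1, Q * C[, j])
    }
    f1 <- logistic_loglik(X1, y, ridge_lambda)
    if (f1$separated) any_sep <<- TRUE
    (f1$loglik - f0$loglik) / log(10)
  }, 0)
  if (any_sep) {
    warning("complete separation detected; ridge penalty (lambda = ",
            ridge_lambda, ") applied")
  }
  scan_result(pos, pmax(0, lod), trait = trait_name, model = "binary",
              covar = covar_tag(cov), n = length(y))
}

#' Scans under the three sex-covariate models
#'
#' Runs the plain scan, the scan with sex as an additive covariate, and
#' the scan with sex as an interactive covariate.  The three models are
#' nested, so position-wise `interactive >= additive >= 0`.
#'
#' @param trait Trait values (quantitative, or 0/1 when `model =
#'   "binary"`).
#' @param probs A `genoprob_grid`.
#' @param sex `"F"`/`"M"` per grid individual.
#' @param model `"hk"` or `"binary"`.
#' @param trait_name Trait label.
#' @return Named list of three [scan_result()]s: `plain`, `additive`,
#'   `interactive`.
#' @export
scan_with_sex_models <- function(trait, probs, sex, model = c("hk", "binary"),
                                 trait_name = "trait") {
  model <- match.arg(model)
  scan_fun <- if (model == "hk") scan_hk else scan_binary
  used <- is.finite(trait)
  if (length(unique(sex[used])) < 2) {
    warning("only one sex present; returning the plain scan for all models")
    plain <- scan_fun(trait, probs, NULL, trait_name)
    return(list(plain = plain, additive = plain, interactive = plain))
  }
  sx <- as.numeric(sex == "M")
  list(
    plain = scan_fun(trait, probs, NULL, trait_name),
    additive = scan_fun(trait, probs,
                        covariate_spec("sex", sx, "additive"), trait_name),
    interactive = scan_fun(trait, probs,
                           covariate_spec("sex", sx, "interactive"), trait_name)
  )
}
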