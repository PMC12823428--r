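# Internal numerical helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp requires a >= b")
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

# Two-sided normal p from a z score, stable in the far tail.
#' @keywords internal
p_from_z <- function(z) {
  lp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  exp(pmin(lp, 0))
}

#' Inverse normal tail: z from a two-sided p value
#'
#' Returns the positive z score whose two-sided normal p value equals `p`,
#' evaluated in log space so that p values down to the smallest representable
#' double (~1e-308) are handled without underflow. Used to reconstruct
#' standard errors from printed odds ratios and p values.
#'
#' @param p Two-sided p value(s) in (0, 1).
#' @return Positive z score(s).
#' @examples
#' z_from_p(0.05)            # ~1.96
#' z_from_p(9.7e-177)        # ~28.3
#' @export
z_from_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly in (0, 1)")
  stats::qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
}

# Logistic ML fit via stats::glm.fit with Wald standard errors.
# X must include the intercept column. Returns coefficients, se,
# convergence and a separation flag (fitted probabilities pinned at 0/1).
#' @keywords internal
fit_logistic <- function(X, y, weights = NULL, offset = NULL) {
  if (is.null(weights)) weights <- rep.int(1, length(y))
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, weights = weights, offset = offset,
    family = stats::binomial(), control = stats::glm.control(maxit = 50)
  ))
  mu <- fit$fitted.values
  separated <- any(mu < 1e-10 | mu > 1 - 1e-10) || any(abs(fit$coefficients) > 20, na.rm = TRUE)
  # Wald covariance from the weighted cross-product at the MLE
  w <- fit$weights                      # IRLS weights mu(1-mu)*prior
  ok <- !is.na(fit$coefficients)
  se <- rep(NA_real_, ncol(X))
  if (fit$converged && all(ok)) {
    XtWX <- crossprod(X * sqrt(w))
    cv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(diag(cv))
  }
  list(beta = fit$coefficients, se = se,
       converged = fit$converged, separated = separated,
       deviance = fit$deviance, aic = fit$aic, fitted = mu)
}

# Gaussian OLS fit (quantitative traits) with classical standard errors.
#' @keywords internal
fit_linear <- function(X, y) {
  fit <- stats::lm.fit(x = X, y = y)
  ok <- !is.na(fit$coefficients)
  rdf <- length(y) - sum(ok)
  s2 <- sum(fit$residuals^2) / rdf
  se <- rep(NA_real_, ncol(X))
  if (all(ok)) {
    cv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(diag(cv) * s2)
  }
  list(beta = fit$coefficients, se = se, converged = all(ok), separated = FALSE)
}

# Harmonize a set of effect/other allele records to reference alleles.
# Returns a sign multiplier (+1 match, -1 swapped) or NA when the variant
# cannot be harmonized. Palindromic (A/T, C/G) variants are resolved by
# effect-allele frequency when it is informative (|eaf - 0.5| > freq_margin
# in both sets), otherwise dropped.
#' @keywords internal
harmonize_sign <- function(ea_ref, oa_ref, ea, oa,
                           eaf_ref = NULL, eaf = NULL, freq_margin = 0.08) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  n <- length(ea)
  out <- rep(NA_real_, n)
  pal <- function(a, b) comp[a] == b
  for (i in seq_len(n)) {
    if (is.na(ea[i]) || is.na(oa[i])) next
    if (pal(ea[i], oa[i])) {
      # palindromic: alleles alone cannot orient the strand
      if (is.null(eaf_ref) || is.null(eaf) ||
          is.na(eaf_ref[i]) || is.na(eaf[i]) ||
          abs(eaf_ref[i] - 0.5) <= freq_margin ||
          abs(eaf[i] - 0.5) <= freq_margin) next
      out[i] <- if (sign(eaf_ref[i] - 0.5) == sign(eaf[i] - 0.5)) 1 else -1
    } else if (ea[i] == ea_ref[i] && oa[i] == oa_ref[i]) {
      out[i] <- 1
    } else if (ea[i] == oa_ref[i] && oa[i] == ea_ref[i]) {
      out[i] <- -1
    } else if (!is.na(comp[ea[i]]) && !is.na(comp[oa[i]]) &&
               comp[ea[i]] == ea_ref[i] && comp[oa[i]] == oa_ref[i]) {
      out[i] <- 1                       # strand flip, same orientation
    } else if (!is.na(comp[ea[i]]) && !is.na(comp[oa[i]]) &&
               comp[ea[i]] == oa_ref[i] && comp[oa[i]] == ea_ref[i]) {
      out[i] <- -1
    }
  }
  unname(out)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a given seed without disturbing the caller's RNG state.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}
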