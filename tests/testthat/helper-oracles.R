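# Independent reference implementations used as oracles. These deliberately
# avoid the code paths they check: direct enumeration, hand-rolled IRLS,
# naive arithmetic.

# Exact conditional HWE p by brute-force enumeration over all genotype
# configurations compatible with the observed allele counts, using plain
# choose() products (no shared code with hwe_exact_p).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  configs <- list()
  for (het in 0:min(nA, 2 * n - nA)) {
    if ((nA - het) %% 2 != 0) next
    aa_ <- (nA - het) / 2
    bb_ <- n - aa_ - het
    if (aa_ < 0 || bb_ < 0) next
    configs[[length(configs) + 1]] <- c(aa_, het, bb_)
  }
  prob <- vapply(configs, function(cf) {
    # multinomial count of genotype assignments x 2^het allele orderings,
    # conditioned on allele counts
    exp(lchoose(n, cf[1]) + lchoose(n - cf[1], cf[2]) + cf[2] * log(2) -
          lchoose(2 * n, nA))
  }, numeric(1))
  prob <- prob / sum(prob)
  obs <- which(vapply(configs, function(cf) cf[2] == n_Aa, logical(1)))
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

# Logistic regression by hand-rolled Newton-Raphson IRLS.
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- t(X) %*% (X * W)
    score <- t(X) %*% (y - mu)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  list(beta = as.vector(beta), se = as.vector(se))
}

# One-sided (enrichment) Fisher p by summing the hypergeometric pmf.
oracle_fisher_greater <- function(a, b, c0, d0) {
  # P(X >= a) with X ~ Hypergeom(white = a+c0, black = b+d0, drawn = a+b)
  sum(dhyper(a:min(a + b, a + c0), a + c0, b + d0, a + b))
}

# Benjamini-Hochberg by the textbook step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Small standard architectures used across tests
null_arch <- function(n_variants = 200L, n_blocks = 10L, block_r = 0,
                      seed = 1L) {
  gen_architecture(
    n_variants = n_variants, n_blocks = n_blocks, block_r = block_r,
    risk_haplotype = list(variants = c(1L, 2L), logor_mediator = 0,
                          logor_outcome = 0),
    mediator_logor = 0, seed = seed)
}

effect_arch <- function(logor_outcome = 0.47, logor_mediator = 0,
                        mediator_logor = 0, n_variants = 20L,
                        block_r = 0.5, seed = 1L, ...) {
  gen_architecture(
    n_variants = n_variants, n_blocks = 2L, block_r = block_r,
    maf_range = c(0.2, 0.4),
    risk_haplotype = list(variants = c(1L, 3L),
                          logor_mediator = logor_mediator,
                          logor_outcome = logor_outcome),
    mediator_logor = mediator_logor, seed = seed, ...)
}

covar_cols <- function(bundle) bundle$phenotypes[, c("age", "sex", "bmi")]
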