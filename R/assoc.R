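# Per-variant association scans: variant QC with reason codes, the exact
# conditional Hardy-Weinberg test, covariate-adjusted logistic / linear scans
# (with optional conditioning columns), genomic inflation, and the
# delta-method odds-ratio confidence interval.

#' Variant QC thresholds
#'
#' @param mac_min Minimum minor-allele count per case and per control arm;
#'   the filter is strict (`MAC > mac_min` required), so the default 5 drops
#'   variants with five or fewer minor alleles in either arm.
#' @param max_missing Maximum per-variant genotype missingness fraction
#'   (strict `<`).
#' @param hwe_p_floor Variants with exact Hardy-Weinberg p below this floor
#'   are dropped.
#' @param maf_min Minimum minor allele frequency (used by pQTL-style scans;
#'   set 0 to disable).
#' @param max_sample_missing Maximum per-sample missingness fraction; samples
#'   above it are removed before variant filters.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(mac_min = 5L, max_missing = 0.03,
                          hwe_p_floor = 1e-6, maf_min = 0,
                          max_sample_missing = 0.05) {
  stopifnot(mac_min >= 0, max_missing >= 0, max_missing <= 1,
            hwe_p_floor >= 0, hwe_p_floor <= 1,
            maf_min >= 0, maf_min < 0.5,
            max_sample_missing >= 0, max_sample_missing <= 1)
  structure(list(mac_min = as.integer(mac_min), max_missing = max_missing,
                 hwe_p_floor = hwe_p_floor, maf_min = maf_min,
                 max_sample_missing = max_sample_missing),
            class = "qc_thresholds")
}

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts: the p
#' value is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' No mid-p correction is applied.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, summing to >= 1).
#' @return Exact p value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa                    # count of allele A
  na <- 2 * n_aa + n_Aa
  if (nA > na) { tmp <- nA; nA <- na; na <- tmp }  # exact label symmetry
  rare <- min(nA, na)
  het <- seq.int(rare %% 2, rare, by = 2)  # feasible heterozygote counts
  # log conditional probability of each heterozygote count given allele counts
  logp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((na - het) / 2 + 1) + het * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - logsumexp(logp))        # normalize exactly
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Apply variant and sample QC filters
#'
#' Partitions variants into kept and dropped sets. Every dropped variant
#' carries exactly one primary reason code, checked in the order
#' `monomorphic`, `mac_case`, `mac_control`, `missingness`, `hwe`, `maf`.
#' For quantitative traits (`phenotype = NULL`) the minor-allele-count arm
#' filters are skipped.
#'
#' @param genotypes Individuals x variants dosage matrix (0/1/2, NA allowed).
#' @param phenotype Binary 0/1 vector aligned with rows, or NULL.
#' @param thresholds A [qc_thresholds()].
#' @return List with `kept` (filtered genotype matrix), `kept_ids`,
#'   `dropped` (data.frame variant/reason), `samples_kept` (row index).
#' @export
qc_variants <- function(genotypes, phenotype = NULL,
                        thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!is.null(phenotype) && length(phenotype) != nrow(genotypes))
    stop("genotype and phenotype sample sets are misaligned")
  smiss <- rowMeans(is.na(genotypes))
  keep_s <- smiss <= thresholds$max_sample_missing
  G <- genotypes[keep_s, , drop = FALSE]
  y <- if (is.null(phenotype)) NULL else phenotype[keep_s]

  ids <- colnames(G) %||% as.character(seq_len(ncol(G)))
  reason <- character(ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    obs <- !is.na(g)
    ac <- sum(g[obs]); an <- 2 * sum(obs)
    if (an == 0) { reason[j] <- "monomorphic"; next }
    maf <- min(ac, an - ac) / an
    mac_tot <- min(ac, an - ac)
    if (mac_tot == 0) { reason[j] <- "monomorphic"; next }
    minor_is_alt <- ac <= an - ac
    if (!is.null(y)) {
      mac_arm <- function(sel) {
        gi <- g[obs & sel]
        aci <- sum(gi); ani <- 2 * length(gi)
        if (minor_is_alt) aci else ani - aci
      }
      if (mac_arm(y == 1) <= thresholds$mac_min) { reason[j] <- "mac_case"; next }
      if (mac_arm(y == 0) <= thresholds$mac_min) { reason[j] <- "mac_control"; next }
    }
    vmiss <- mean(is.na(g))
    if (vmiss > 0 && vmiss >= thresholds$max_missing) {
      reason[j] <- "missingness"; next   # kept variants satisfy miss < max
    }
    cnt <- c(sum(g[obs] == 0), sum(g[obs] == 1), sum(g[obs] == 2))
    if (hwe_exact_p(cnt[1], cnt[2], cnt[3]) < thresholds$hwe_p_floor) {
      reason[j] <- "hwe"; next
    }
    if (maf <= thresholds$maf_min && thresholds$maf_min > 0) {
      reason[j] <- "maf"; next
    }
  }
  kept <- reason == ""
  list(kept = G[, kept, drop = FALSE], kept_ids = ids[kept],
       dropped = data.frame(variant = ids[!kept], reason = reason[!kept],
                            stringsAsFactors = FALSE),
       samples_kept = which(keep_s))
}

#' Covariate-adjusted per-variant association scan
#'
#' Fits, for each variant, `trait ~ dosage + covariates (+ condition_on)` by
#' maximum likelihood — logistic for binary traits (beta is the per-allele
#' log-OR with Wald standard error) or ordinary least squares for
#' quantitative traits (beta per allele in trait units). Samples missing a
#' variant's dosage are dropped for that variant (per-variant complete-case).
#' Perfectly separated or non-converged fits are flagged and their p set
#' missing.
#'
#' @param genotypes Individuals x variants dosage matrix.
#' @param map Variant map data.frame (`id, chrom, pos, ea, oa`) aligned with
#'   columns, or NULL for a minimal map.
#' @param trait Outcome vector (0/1 for binary).
#' @param covariates Data frame / matrix of numeric covariates, or NULL.
#' @param family `"binary"` or `"quantitative"`.
#' @param condition_on Optional extra numeric columns (e.g. haplotype count)
#'   added to the model for conditional scans.
#' @return Data frame with one row per variant: `id, chrom, pos, ea, oa, eaf,
#'   beta, se, z, p, n, n_cases, flag`.
#' @export
assoc_scan <- function(genotypes, map = NULL, trait, covariates = NULL,
                       family = c("binary", "quantitative"),
                       condition_on = NULL) {
  family <- match.arg(family)
  n <- nrow(genotypes)
  if (length(trait) != n) stop("trait length does not match genotype rows")
  C <- NULL
  if (!is.null(covariates)) C <- as.matrix(covariates)
  if (!is.null(condition_on)) C <- cbind(C, as.matrix(condition_on))
  if (is.null(map)) {
    map <- data.frame(id = colnames(genotypes) %||% as.character(seq_len(ncol(genotypes))),
                      chrom = NA_integer_, pos = NA_integer_,
                      ea = NA_character_, oa = NA_character_,
                      stringsAsFactors = FALSE)
  }
  base <- cbind(`(Intercept)` = 1, C)
  qr_rank <- qr(base)$rank
  if (qr_rank < ncol(base)) stop("covariate matrix is rank deficient")

  m <- ncol(genotypes)
  out <- data.frame(
    id = map$id, chrom = map$chrom, pos = map$pos, ea = map$ea, oa = map$oa,
    eaf = NA_real_, beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
    n = NA_integer_, n_cases = NA_integer_, flag = "", stringsAsFactors = FALSE
  )
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    obs <- which(!is.na(g) & !is.na(trait))
    if (!is.null(C)) obs <- obs[stats::complete.cases(C[obs, , drop = FALSE])]
    gi <- g[obs]; yi <- trait[obs]
    out$n[j] <- length(obs)
    out$eaf[j] <- mean(gi) / 2
    if (family == "binary") out$n_cases[j] <- sum(yi == 1)
    if (length(unique(gi)) < 2) { out$flag[j] <- "monomorphic"; next }
    X <- cbind(1, gi, if (!is.null(C)) C[obs, , drop = FALSE])
    fit <- if (family == "binary") fit_logistic(X, yi) else fit_linear(X, yi)
    if (!fit$converged) { out$flag[j] <- "nonconverged"; next }
    if (fit$separated) { out$flag[j] <- "separated"; next }
    b <- fit$beta[2]; s <- fit$se[2]
    if (is.na(s) || s <= 0) { out$flag[j] <- "nonconverged"; next }
    out$beta[j] <- b; out$se[j] <- s; out$z[j] <- b / s
    out$p[j] <- p_from_z(b / s)
  }
  out
}

#' Genomic inflation factor
#'
#' lambda = median(chi-square statistics) / 0.4549364 (the null median of a
#' 1-df chi-square). Supply either p values or z scores.
#'
#' @param p Two-sided p values, or NULL.
#' @param z z scores, or NULL (one of the two required).
#' @return lambda (non-negative scalar).
#' @export
genomic_lambda <- function(p = NULL, z = NULL) {
  if (is.null(z)) {
    if (is.null(p)) stop("supply p or z")
    p <- p[is.finite(p)]
    if (length(p) < 10) stop("need at least 10 values")
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  } else {
    z <- z[is.finite(z)]
    if (length(z) < 10) stop("need at least 10 values")
    chisq <- z^2
  }
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Odds ratio with delta-method confidence interval
#'
#' OR = exp(beta); the 95% bounds are `exp(beta) -/+ 1.96 * se * exp(beta)`
#' (the delta-method interval on the OR scale, not `exp(beta -/+ 1.96 se)`).
#'
#' @param beta Log-odds-ratio estimate(s).
#' @param se Standard error(s), non-negative.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `or, lower, upper`.
#' @export
or_ci <- function(beta, se, level = 0.95) {
  if (any(se < 0)) stop("se must be non-negative")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  or <- exp(beta)
  data.frame(or = or, lower = or - zq * se * or, upper = or + zq * se * or)
}
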