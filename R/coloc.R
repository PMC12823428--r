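# Single-causal-variant approximate-Bayes-factor colocalization and the
# druggability triangulation report.

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a N(0, W^2) effect
#' prior, the Bayes factor in favor of association is
#' `sqrt(se^2/(se^2+W^2)) * exp(z^2 W^2 / (2 (se^2+W^2)))`; the log is
#' computed directly so large z scores do not overflow.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param W Prior standard deviation of the true effect, > 0.
#' @return log approximate Bayes factor(s).
#' @export
abf <- function(beta, se, W = 0.2) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(W <= 0)) stop("prior sd W must be positive")
  z2 <- (beta / se)^2
  r <- W^2 / (se^2 + W^2)
  0.5 * log(1 - r) + z2 * r / 2
}

#' Colocalization of two traits in a region (single causal variant)
#'
#' Computes per-variant log approximate Bayes factors for each trait and
#' combines them under the five-hypothesis model: H0 no association, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant. Posterior probabilities use prior per-variant
#' probabilities `p1`, `p2` (single-trait) and `p12` (shared), with all sums
#' in log-sum-exp arithmetic. Variants are matched by id and harmonization is
#' unnecessary because only squared z scores enter the Bayes factors.
#'
#' @param trait1,trait2 Summary-stat data frames (`id, beta, se`; rows
#'   restricted to the region of interest). `trait1` conventionally the
#'   disease, `trait2` the protein.
#' @param priors Numeric vector `c(p1, p2, p12)`,
#'   default `c(1e-4, 1e-4, 1e-5)`.
#' @param W1,W2 Per-trait effect prior standard deviations (0.2 for binary
#'   log-ORs, 0.15 per standardized protein unit).
#' @param thresholds `c(colocalized, suggestive)` PP.H4 category cuts;
#'   default `c(0.8, 0.5)`, use `c(0.9, 0.5)` for the strict reading.
#' @return A `coloc_result` list: `pp` (named PP.H0..PP.H4, summing to 1),
#'   `category` (`colocalized`/`suggestive`/`none`), `n_variants`,
#'   `priors`, per-variant `labf` data frame.
#' @export
coloc_region <- function(trait1, trait2, priors = c(1e-4, 1e-4, 1e-5),
                         W1 = 0.2, W2 = 0.15, thresholds = c(0.8, 0.5)) {
  common <- intersect(trait1$id, trait2$id)
  if (!length(common)) stop("no common variants in the region")
  t1 <- trait1[match(common, trait1$id), ]
  t2 <- trait2[match(common, trait2$id), ]
  l1 <- abf(t1$beta, t1$se, W1)
  l2 <- abf(t2$beta, t2$se, W2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over i != j of BF1_i * BF2_j = S1*S2 - S12
  s3 <- if (length(common) > 1) logdiffexp(s1 + s2, s12) else -Inf
  lp <- log(priors)
  lh <- c(H0 = 0,
          H1 = lp[1] + s1,
          H2 = lp[2] + s2,
          H3 = lp[1] + lp[2] + s3,
          H4 = lp[3] + s12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP.", names(lh))
  category <- if (pp["PP.H4"] > thresholds[1]) "colocalized"
  else if (pp["PP.H4"] > thresholds[2]) "suggestive" else "none"
  structure(list(pp = pp, category = category, n_variants = length(common),
                 priors = priors,
                 labf = data.frame(id = common, labf1 = l1, labf2 = l2,
                                   stringsAsFactors = FALSE)),
            class = "coloc_result")
}

#' Assemble the triangulation report
#'
#' One row per protein passing the dual-support gate: nominal PWAS support
#' (two-sided p < 0.05), FDR-significant primary MR (q < `q_max`), and
#' consistent effect direction between the two. Each record carries the PWAS
#' evidence tier (`bonferroni` if p is below the Bonferroni threshold, else
#' `fdr` if q < 0.05, else `nominal`), the MR sensitivity flags, the
#' colocalization category and the druggability tier (proteins absent from
#' the tier table are labelled `Not classified`). Proteins with an undefined
#' direction (zero effect) are excluded with a reason.
#'
#' @param pwas [pwas_scan()] results (`protein, beta, p, q` and the
#'   `bonferroni_threshold` attribute, or pass `bonf_thr`).
#' @param mr [mr_panel()] results.
#' @param coloc Named list of `coloc_result` objects per protein (optional).
#' @param tiers Data frame `protein, tier` (optional).
#' @param q_max MR FDR gate (default 0.05).
#' @param bonf_thr PWAS Bonferroni threshold; defaults to the attribute on
#'   `pwas`, else `0.05 / nrow(pwas)`.
#' @return List: `records` (one row per included protein) and `excluded`
#'   (protein/reason).
#' @export
triangulate <- function(pwas, mr, coloc = NULL, tiers = NULL, q_max = 0.05,
                        bonf_thr = NULL) {
  if (is.null(bonf_thr))
    bonf_thr <- attr(pwas, "bonferroni_threshold") %||% (0.05 / nrow(pwas))
  excluded <- data.frame(protein = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  recs <- list()
  results <- attr(mr, "results")
  for (k in seq_len(nrow(mr))) {
    pn <- mr$protein[k]
    if (!isTRUE(mr$fdr_sig[k])) next
    i <- match(pn, pwas$protein)
    if (is.na(i) || !is.finite(pwas$p[i]) || pwas$p[i] >= 0.05) {
      excluded <- rbind(excluded, data.frame(protein = pn, reason = "no_pwas_support"))
      next
    }
    if (pwas$beta[i] == 0 || mr$beta[k] == 0) {
      excluded <- rbind(excluded, data.frame(protein = pn, reason = "zero_effect"))
      next
    }
    if (sign(pwas$beta[i]) != sign(mr$beta[k])) {
      excluded <- rbind(excluded, data.frame(protein = pn, reason = "direction_mismatch"))
      next
    }
    tier_pwas <- if (pwas$p[i] < bonf_thr) "bonferroni"
    else if (!is.na(pwas$q[i]) && pwas$q[i] < 0.05) "fdr" else "nominal"
    r <- results[[pn]]
    sens_flag <- function(method) {
      if (is.null(r)) return(NA)
      e <- r$estimates[r$estimates$method == method, ]
      if (!nrow(e) || !is.finite(e$p)) return(NA)
      e$p < 0.05 && sign(e$beta) == sign(mr$beta[k])
    }
    cc <- if (!is.null(coloc) && pn %in% names(coloc))
      coloc[[pn]]$category else "none"
    tier_drug <- "Not classified"
    if (!is.null(tiers)) {
      j <- match(pn, tiers$protein)
      if (!is.na(j)) tier_drug <- tiers$tier[j]
    }
    recs[[pn]] <- data.frame(
      protein = pn,
      direction = if (mr$beta[k] > 0) "+" else "-",
      pwas_tier = tier_pwas,
      mr_primary = TRUE,
      mr_sens_ok = isTRUE(mr$sens_sig[k]),
      wm_ok = sens_flag("weighted_median"),
      ml_ok = sens_flag("max_likelihood"),
      egger_ok = sens_flag("egger"),
      egger_intercept_ok = is.finite(mr$egger_intercept_p[k]) &&
        mr$egger_intercept_p[k] > 0.05,
      q_test_ok = is.finite(mr$q_het_p[k]) && mr$q_het_p[k] > 0.05,
      replicated = isTRUE(mr$replicated[k]),
      coloc = cc,
      druggability = tier_drug,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records, excluded = excluded)
}
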