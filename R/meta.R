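# Fixed-effects inverse-variance meta-analysis with genomic-control
# correction, greedy lead-variant extraction, Bonferroni replication, and
# the observed-to-liability heritability conversion.

#' Fixed-effects inverse-variance meta-analysis of association scans
#'
#' Pools per-variant effects across studies with weights `w_j = 1/se_j^2`:
#' pooled beta = sum(w beta)/sum(w), pooled se = 1/sqrt(sum(w)). Alleles are
#' harmonized to the first study carrying each variant (swapped alleles flip
#' the sign and frequency; palindromic variants are resolved by allele
#' frequency or dropped). With `gc = TRUE` each study's standard errors are
#' first inflated by `sqrt(max(lambda, 1))`, where lambda is that study's
#' genomic inflation factor; genomic control is applied per study only.
#' Variants present in fewer than two studies are excluded unless
#' `passthrough = TRUE`, in which case they are passed through flagged.
#'
#' @param records_by_study List of association data frames in the
#'   [assoc_scan()] dialect (`id, ea, oa, eaf, beta, se, ...`).
#' @param gc Apply per-study genomic-control se inflation?
#' @param passthrough Keep single-study variants (flagged)?
#' @param meta_gc Additionally apply genomic control to the pooled z scores
#'   (off by default).
#' @return Data frame: `id, chrom, pos, ea, oa, eaf, beta, se, z, p,
#'   n_studies, n, n_cases, het_q, het_p, single_study`, plus a `lambda`
#'   attribute with the per-study inflation factors applied.
#' @export
meta_fixed <- function(records_by_study, gc = TRUE, passthrough = FALSE,
                       meta_gc = FALSE) {
  stopifnot(is.list(records_by_study), length(records_by_study) >= 1)
  lam <- vapply(records_by_study, function(d) {
    ok <- is.finite(d$beta) & is.finite(d$se) & d$se > 0
    if (sum(ok) >= 10) genomic_lambda(z = d$beta[ok] / d$se[ok]) else 1
  }, numeric(1))
  infl <- if (gc) sqrt(pmax(lam, 1)) else rep(1, length(lam))

  ref <- NULL      # per-variant reference alleles from first appearance
  rows <- list()
  dropped <- character(0)
  for (s in seq_along(records_by_study)) {
    d <- records_by_study[[s]]
    d <- d[is.finite(d$beta) & is.finite(d$se) & d$se > 0, , drop = FALSE]
    if (!nrow(d)) next
    d$se <- d$se * infl[s]
    if (is.null(ref)) {
      ref <- d[, intersect(c("id", "chrom", "pos", "ea", "oa", "eaf"),
                           names(d)), drop = FALSE]
    } else {
      new <- !(d$id %in% ref$id)
      if (any(new))
        ref <- rbind(ref, d[new, names(ref), drop = FALSE])
    }
    i <- match(d$id, ref$id)
    sgn <- harmonize_sign(ref$ea[i], ref$oa[i], d$ea, d$oa,
                          eaf_ref = ref$eaf[i], eaf = d$eaf)
    dropped <- c(dropped, d$id[is.na(sgn)])
    keep <- !is.na(sgn)
    rows[[s]] <- data.frame(
      id = d$id[keep], beta = d$beta[keep] * sgn[keep], se = d$se[keep],
      n = if ("n" %in% names(d)) d$n[keep] else NA_integer_,
      n_cases = if ("n_cases" %in% names(d)) d$n_cases[keep] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) return(data.frame())
  sp <- split(all, all$id)
  res <- lapply(sp, function(d) {
    w <- 1 / d$se^2
    b <- sum(w * d$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    q <- sum(w * (d$beta - b)^2)
    data.frame(id = d$id[1], beta = b, se = se,
               n_studies = nrow(d),
               n = sum(d$n), n_cases = sum(d$n_cases),
               het_q = q,
               het_p = if (nrow(d) > 1) stats::pchisq(q, nrow(d) - 1, lower.tail = FALSE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$single_study <- res$n_studies < 2
  if (!passthrough) res <- res[!res$single_study, , drop = FALSE]
  res$z <- res$beta / res$se
  if (meta_gc) {
    lam_meta <- genomic_lambda(z = res$z)
    if (lam_meta > 1) { res$se <- res$se * sqrt(lam_meta); res$z <- res$beta / res$se }
  }
  res$p <- p_from_z(res$z)
  i <- match(res$id, ref$id)
  res <- cbind(res[, "id", drop = FALSE],
               ref[i, setdiff(names(ref), "id"), drop = FALSE],
               res[, setdiff(names(res), "id"), drop = FALSE])
  rownames(res) <- NULL
  attr(res, "lambda") <- lam
  attr(res, "dropped_unharmonized") <- unique(dropped)
  res
}

#' Greedy lead-variant extraction
#'
#' Repeatedly takes the smallest-p genome-wide-significant variant and
#' excludes all variants within `window_bp` of it on the same chromosome,
#' until no significant variants remain. Output order is by increasing p and
#' is invariant to input ordering (ties broken by id).
#'
#' @param meta Data frame with `id, chrom, pos, p` (e.g. from [meta_fixed()]).
#' @param window_bp Half-width of the exclusion window (default 500 kb).
#' @param alpha Significance threshold (default 5e-8).
#' @return The lead rows of `meta`, ordered by p.
#' @export
lead_variants <- function(meta, window_bp = 5e5, alpha = 5e-8) {
  if (is.null(meta) || !nrow(meta)) return(meta[integer(0), , drop = FALSE])
  cand <- meta[is.finite(meta$p) & meta$p < alpha, , drop = FALSE]
  cand <- cand[order(cand$p, cand$id), , drop = FALSE]
  leads <- integer(0)
  while (nrow(cand)) {
    leads <- c(leads, which(meta$id == cand$id[1])[1])
    keep <- !(cand$chrom == cand$chrom[1] &
                abs(cand$pos - cand$pos[1]) <= window_bp)
    cand <- cand[keep, , drop = FALSE]
  }
  out <- meta[leads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni replication test for lead variants
#'
#' A lead replicates when its replication p value is below
#' `0.05 / n_leads` and its effect direction matches discovery. Leads absent
#' from the replication set fail with reason `absent`.
#'
#' @param leads Data frame of discovery leads (`id, ea, oa, beta`).
#' @param replication_stats Data frame in the same dialect.
#' @param alpha Family-wise level before Bonferroni division (default 0.05).
#' @return Data frame `id, p_rep, beta_rep, threshold, pass, reason`.
#' @export
replicate_leads <- function(leads, replication_stats, alpha = 0.05) {
  n_leads <- nrow(leads)
  thr <- alpha / max(n_leads, 1)
  i <- match(leads$id, replication_stats$id)
  out <- data.frame(id = leads$id, p_rep = NA_real_, beta_rep = NA_real_,
                    threshold = thr, pass = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_leads)) {
    if (is.na(i[k])) { out$reason[k] <- "absent"; next }
    r <- replication_stats[i[k], ]
    sgn <- harmonize_sign(leads$ea[k], leads$oa[k], r$ea, r$oa,
                          eaf_ref = leads$eaf[k] %||% NA, eaf = r$eaf %||% NA)
    if (is.na(sgn)) { out$reason[k] <- "unharmonizable"; next }
    out$p_rep[k] <- r$p
    out$beta_rep[k] <- r$beta * sgn
    if (!is.finite(r$p)) { out$reason[k] <- "missing_p"; next }
    same_dir <- sign(out$beta_rep[k]) == sign(leads$beta[k])
    out$pass[k] <- r$p < thr && same_dir
    if (!out$pass[k])
      out$reason[k] <- if (!same_dir) "direction" else "threshold"
  }
  out
}

#' Observed-scale to liability-scale heritability conversion
#'
#' Applies `h2_liab = h2_obs * K(1-K)/z^2 * K(1-K)/(P(1-P))` where `K` is the
#' population prevalence, `P` the sample prevalence and `z` the standard
#' normal density at the K-quantile.
#'
#' @param h2_obs Observed-scale heritability.
#' @param K Population prevalence in (0, 1).
#' @param P Sample (case-control) prevalence in (0, 1).
#' @return List with `K, P, h2_obs, z_density, h2_liab`.
#' @export
h2_liability <- function(h2_obs, K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("K and P must lie strictly in (0, 1)")
  z <- stats::dnorm(stats::qnorm(K))
  list(K = K, P = P, h2_obs = h2_obs, z_density = z,
       h2_liab = h2_obs * (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P))))
}
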