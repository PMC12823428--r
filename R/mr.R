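# cis-pQTL instrument construction (LD clumping, F-statistic, pleiotropy and
# cis filters) and the two-sample MR estimator battery: Wald ratio, IVW,
# weighted median, maximum likelihood, MR-Egger, with Egger-intercept and
# Cochran's Q diagnostics, plus the discovery/sensitivity/replication panel.

#' Greedy LD-based clumping of an association scan
#'
#' Orders significant variants by p value; repeatedly takes the most
#' significant remaining variant as an index and removes all other
#' significant variants within `window_bp` on the same chromosome whose LD
#' r-squared with it reaches `r2_max`. Returned indices are mutually
#' independent at the stated r-squared within the window. LD is computed
#' from a genotype reference; variants absent from it are dropped with
#' reason `no_ld_reference`.
#'
#' @param assoc Association data frame (`id, chrom, pos, p`, from
#'   [assoc_scan()]).
#' @param genotypes Reference individuals x variants dosage matrix with
#'   column names matching `assoc$id`.
#' @param r2_max LD threshold (default 0.2); variants at or above it are
#'   clumped away.
#' @param window_bp Half-width of the clumping window (default 250 kb).
#' @param alpha Significance threshold (default 5e-8).
#' @return List: `index` (data frame of retained index variants) and
#'   `dropped` (variant/reason).
#' @export
ld_clump <- function(assoc, genotypes, r2_max = 0.2, window_bp = 2.5e5,
                     alpha = 5e-8) {
  sig <- assoc[is.finite(assoc$p) & assoc$p < alpha, , drop = FALSE]
  dropped <- data.frame(variant = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  in_ref <- sig$id %in% colnames(genotypes)
  if (any(!in_ref))
    dropped <- rbind(dropped, data.frame(variant = sig$id[!in_ref],
                                         reason = "no_ld_reference"))
  sig <- sig[in_ref, , drop = FALSE]
  sig <- sig[order(sig$p, sig$id), , drop = FALSE]
  keep <- character(0)
  while (nrow(sig)) {
    idx <- sig[1, ]
    keep <- c(keep, idx$id)
    sig <- sig[-1, , drop = FALSE]
    if (!nrow(sig)) break
    win <- sig$chrom == idx$chrom & abs(sig$pos - idx$pos) <= window_bp
    if (any(win)) {
      r2 <- suppressWarnings(stats::cor(genotypes[, idx$id],
                                        genotypes[, sig$id[win], drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      clumped <- sig$id[win][!is.na(r2) & as.vector(r2) >= r2_max]
      if (length(clumped)) {
        dropped <- rbind(dropped, data.frame(variant = clumped,
                                             reason = "ld_clumped"))
        sig <- sig[!(sig$id %in% clumped), , drop = FALSE]
      }
    }
  }
  list(index = assoc[match(keep, assoc$id), , drop = FALSE], dropped = dropped)
}

#' Build MR instruments from clumped pQTLs
#'
#' Joins clumped exposure (protein) associations to outcome summary
#' statistics (allele-harmonized), computes the approximate F-statistic
#' `F = beta_exp^2 / se_exp^2`, and applies three filters: `F >= f_min`
#' (weak-instrument guard), cis location (variant within `cis_bp` of the
#' protein-coding gene, inclusive both ends), and association with fewer
#' than `max_proteins` proteins (pleiotropy guard, strict `<`).
#'
#' @param exposure Clumped pQTL data frame (`id, chrom, pos, ea, oa, eaf,
#'   beta, se`).
#' @param outcome Outcome summary-stat data frame in the same dialect.
#' @param gene List or one-row data frame with `chrom, start, end` for the
#'   protein-coding gene.
#' @param proteins_per_variant Named integer vector: for each variant id, the
#'   number of proteins it is associated with at genome-wide significance
#'   (defaults to 1 when absent).
#' @param f_min Minimum F-statistic (default 10).
#' @param max_proteins Pleiotropy cap (default 5; retained iff `< 5`).
#' @param cis_bp Cis window half-width (default 1 Mb, inclusive).
#' @return List: `instruments` data frame (`id, beta_exp, se_exp, beta_out,
#'   se_out, f_stat, cis, n_proteins`) and `excluded` (variant/reason).
#' @export
build_instruments <- function(exposure, outcome, gene,
                              proteins_per_variant = NULL,
                              f_min = 10, max_proteins = 5L, cis_bp = 1e6) {
  ex <- exposure
  i <- match(ex$id, outcome$id)
  excluded <- data.frame(variant = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  note <- function(v, r) rbind(excluded,
                               data.frame(variant = v, reason = r,
                                          stringsAsFactors = FALSE))
  keep <- rep(TRUE, nrow(ex))
  rows <- vector("list", nrow(ex))
  for (k in seq_len(nrow(ex))) {
    if (is.na(i[k])) { excluded <- note(ex$id[k], "absent_from_outcome"); keep[k] <- FALSE; next }
    out <- outcome[i[k], ]
    sgn <- harmonize_sign(ex$ea[k], ex$oa[k], out$ea, out$oa,
                          eaf_ref = ex$eaf[k] %||% NA, eaf = out$eaf %||% NA)
    if (is.na(sgn)) { excluded <- note(ex$id[k], "unharmonizable"); keep[k] <- FALSE; next }
    f_stat <- ex$beta[k]^2 / ex$se[k]^2
    cis <- ex$chrom[k] == gene$chrom &&
      ex$pos[k] >= gene$start - cis_bp && ex$pos[k] <= gene$end + cis_bp
    npr <- 1L
    if (!is.null(proteins_per_variant) && ex$id[k] %in% names(proteins_per_variant))
      npr <- as.integer(proteins_per_variant[[ex$id[k]]])
    if (!cis) { excluded <- note(ex$id[k], "not_cis"); keep[k] <- FALSE; next }
    if (f_stat < f_min) { excluded <- note(ex$id[k], "weak_instrument"); keep[k] <- FALSE; next }
    if (npr >= max_proteins) { excluded <- note(ex$id[k], "pleiotropic"); keep[k] <- FALSE; next }
    rows[[k]] <- data.frame(id = ex$id[k],
                            beta_exp = ex$beta[k], se_exp = ex$se[k],
                            beta_out = out$beta * sgn, se_out = out$se,
                            f_stat = f_stat, cis = cis, n_proteins = npr,
                            stringsAsFactors = FALSE)
  }
  list(instruments = do.call(rbind, rows[keep]), excluded = excluded)
}

# profile maximum likelihood for the bivariate-normal MR model
#' @keywords internal
mr_ml <- function(bx, by, sx, sy) {
  nll <- function(beta) {
    xi <- (bx / sx^2 + beta * by / sy^2) / (1 / sx^2 + beta^2 / sy^2)
    sum((bx - xi)^2 / sx^2 + (by - beta * xi)^2 / sy^2) / 2
  }
  ivw0 <- sum(by * bx / sy^2) / sum(bx^2 / sy^2)
  opt <- stats::optimize(nll, interval = ivw0 + c(-1, 1) * max(1, 10 * abs(ivw0)),
                         tol = 1e-9)
  b <- opt$minimum
  h <- (nll(b + 1e-4) - 2 * nll(b) + nll(b - 1e-4)) / 1e-8  # profile curvature
  se <- if (h > 0) 1 / sqrt(h) else NA_real_
  c(beta = b, se = se)
}

# weighted median of ratio estimates with parametric-bootstrap se
#' @keywords internal
mr_wm <- function(ratio, w, bx, by, sx, sy, n_boot = 500L, seed = 1L) {
  wmed <- function(x, wt) {
    o <- order(x); x <- x[o]; wt <- wt[o] / sum(wt)
    cw <- cumsum(wt) - wt / 2
    stats::approx(cw, x, xout = 0.5, rule = 2)$y
  }
  est <- wmed(ratio, w)
  bs <- with_local_seed(seed, replicate(n_boot, {
    bxs <- stats::rnorm(length(bx), bx, sx)
    bys <- stats::rnorm(length(by), by, sy)
    wmed(bys / bxs, (bxs / sy)^2)
  }))
  c(beta = est, se = stats::sd(bs))
}

#' Two-sample MR estimator battery for one protein
#'
#' With one instrument reports the Wald ratio `beta_out / beta_exp` with
#' first-order se `se_out / |beta_exp|`. With several instruments reports:
#' inverse-variance-weighted (IVW) estimate with fixed-effect weights
#' `1/se_ratio^2` and multiplicative over-dispersion scaling of the se when
#' Cochran's Q exceeds its degrees of freedom; weighted median (500-draw
#' parametric bootstrap se); profile maximum likelihood under the bivariate
#' normal model; MR-Egger (weighted regression with intercept, weights
#' `1/se_out^2`) with the intercept's two-sided normal test; and Cochran's Q
#' with `df = n_instruments - 1`. Instruments with `beta_exp = 0` are
#' dropped with a reason.
#'
#' @param instruments Data frame from [build_instruments()] (`beta_exp,
#'   se_exp, beta_out, se_out`).
#' @param seed Seed for the weighted-median bootstrap.
#' @param se_model `"overdispersed"` (default): IVW se scaled by
#'   `sqrt(max(Q/df, 1))`, robust to residual heterogeneity but conservative
#'   at the null; `"fixed"`: plain fixed-effect se, exactly calibrated when
#'   instruments are valid.
#' @return An `mr_result` list: `estimates` (method, beta, se, p),
#'   `egger_intercept` (beta, se, p), `q` (statistic, df, p), `n_instruments`,
#'   `instruments`, `primary` ("ivw" or "wald_ratio").
#' @export
mr_battery <- function(instruments, seed = 1L,
                       se_model = c("overdispersed", "fixed")) {
  se_model <- match.arg(se_model)
  ins <- instruments
  if (is.null(ins) || !nrow(ins)) stop("at least one instrument required")
  zero <- ins$beta_exp == 0
  dropped <- ins$id[zero]
  ins <- ins[!zero, , drop = FALSE]
  if (!nrow(ins)) stop("all instruments have zero exposure effect")
  bx <- ins$beta_exp; by <- ins$beta_out; sx <- ins$se_exp; sy <- ins$se_out
  ratio <- by / bx
  se_ratio <- sy / abs(bx)                 # first-order delta method
  n <- nrow(ins)

  row <- function(method, b, s) data.frame(
    method = method, beta = b, se = s,
    p = if (is.na(s) || s <= 0) NA_real_ else p_from_z(b / s),
    stringsAsFactors = FALSE)

  if (n == 1L) {
    est <- row("wald_ratio", ratio, se_ratio)
    return(structure(list(
      estimates = est, egger_intercept = NULL,
      q = data.frame(statistic = NA_real_, df = 0L, p = NA_real_),
      n_instruments = 1L, instruments = ins, dropped = dropped,
      primary = "wald_ratio"), class = "mr_result"))
  }
  w <- 1 / se_ratio^2
  b_ivw <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - b_ivw)^2)
  df <- n - 1L
  phi <- if (se_model == "overdispersed") max(q / df, 1) else 1
  se_ivw <- sqrt(phi / sum(w))
  est <- rbind(
    row("ivw", b_ivw, se_ivw),
    row("weighted_median", NA, NA),
    row("max_likelihood", NA, NA),
    row("egger", NA, NA))
  wm <- mr_wm(ratio, w, bx, by, sx, sy, seed = seed)
  est[est$method == "weighted_median", c("beta", "se")] <- as.list(wm)
  ml <- mr_ml(bx, by, sx, sy)
  est[est$method == "max_likelihood", c("beta", "se")] <- as.list(ml)

  # MR-Egger: orient so all exposure effects are positive, then weighted
  # regression of outcome effects on exposure effects with intercept
  s_or <- sign(bx); bxe <- bx * s_or; bye <- by * s_or
  we <- 1 / sy^2
  eg <- stats::lm(bye ~ bxe, weights = we)
  sm <- summary(eg)
  eg_b <- stats::coef(eg)
  eg_se <- if (sm$sigma > 0) {
    sm$coefficients[, "Std. Error"] / sm$sigma * max(sm$sigma, 1)
  } else sm$coefficients[, "Std. Error"]   # exact fit: zero residual sd
  est[est$method == "egger", c("beta", "se")] <- list(eg_b[2], eg_se[2])
  est$p <- ifelse(is.finite(est$se) & est$se > 0,
                  p_from_z(est$beta / est$se), NA_real_)
  structure(list(
    estimates = est,
    egger_intercept = data.frame(beta = eg_b[1], se = eg_se[1],
                                 p = p_from_z(eg_b[1] / eg_se[1])),
    q = data.frame(statistic = q, df = df,
                   p = stats::pchisq(q, df, lower.tail = FALSE)),
    n_instruments = n, instruments = ins, dropped = dropped,
    primary = "ivw"), class = "mr_result")
}

#' Proteome-wide MR panel with FDR, sensitivity and replication outcomes
#'
#' Runs the estimator battery per protein against the discovery outcome,
#' applies BH FDR across proteins on the primary estimator's p (IVW, or Wald
#' ratio for single-instrument proteins; untestable proteins are excluded
#' from the FDR denominator), and re-tests FDR-significant proteins on the
#' sensitivity outcome (FDR within the re-tested set, `q < q_max`) and the
#' replication outcome (`p < 0.05` and same direction).
#'
#' @param instrument_sets Named list (per protein) of instrument data frames
#'   (discovery outcome already joined), or NULL entries for untestable
#'   proteins.
#' @param sensitivity_sets,replication_sets Optional named lists of
#'   instrument data frames built against the sensitivity / replication
#'   outcome statistics.
#' @param q_max FDR threshold (default 0.05).
#' @param seed Seed passed to the per-protein battery.
#' @return Data frame: one row per protein with primary estimates, q, flags
#'   `fdr_sig, sens_sig, replicated`, diagnostics and instrument counts; the
#'   full `mr_result` objects are attached as attribute `results`.
#' @export
mr_panel <- function(instrument_sets, sensitivity_sets = NULL,
                     replication_sets = NULL, q_max = 0.05, seed = 1L) {
  prots <- names(instrument_sets)
  res <- lapply(prots, function(pn) {
    ins <- instrument_sets[[pn]]
    if (is.null(ins) || !nrow(ins)) return(NULL)
    tryCatch(mr_battery(ins, seed = seed), error = function(e) NULL)
  })
  names(res) <- prots
  testable <- !vapply(res, is.null, logical(1))
  tab <- do.call(rbind, lapply(prots[testable], function(pn) {
    r <- res[[pn]]
    pri <- r$estimates[r$estimates$method == r$primary, ]
    data.frame(protein = pn, method = r$primary,
               beta = pri$beta, se = pri$se, p = pri$p,
               n_instruments = r$n_instruments,
               egger_intercept_p = if (is.null(r$egger_intercept)) NA_real_ else r$egger_intercept$p,
               q_het_p = r$q$p, stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) return(data.frame())
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$fdr_sig <- !is.na(tab$q) & tab$q < q_max
  tab$sens_sig <- NA; tab$replicated <- NA
  run_primary <- function(sets, pn) {
    ins <- sets[[pn]]
    if (is.null(ins) || !nrow(ins)) return(NULL)
    r <- tryCatch(mr_battery(ins, seed = seed), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    r$estimates[r$estimates$method == r$primary, ]
  }
  if (!is.null(sensitivity_sets)) {
    sig <- tab$protein[tab$fdr_sig]
    ps <- vapply(sig, function(pn) {
      pri <- run_primary(sensitivity_sets, pn)
      if (is.null(pri)) NA_real_ else pri$p
    }, numeric(1))
    qs <- stats::p.adjust(ps, method = "BH")
    tab$sens_sig[match(sig, tab$protein)] <- !is.na(qs) & qs < q_max
  }
  if (!is.null(replication_sets)) {
    sig <- tab$protein[tab$fdr_sig]
    for (pn in sig) {
      pri <- run_primary(replication_sets, pn)
      k <- match(pn, tab$protein)
      tab$replicated[k] <- !is.null(pri) && is.finite(pri$p) &&
        pri$p < 0.05 && sign(pri$beta) == sign(tab$beta[k])
    }
  }
  attr(tab, "results") <- res
  tab
}
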