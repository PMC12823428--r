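# Proteome-wide association: preprocessing (missingness filter, mean
# imputation, rank-based inverse-normal transform, standardization),
# per-protein logistic models with optional haplotype adjustment and
# interaction, Bonferroni/BH control, and Fisher/BH pathway enrichment.

#' Rank-based inverse-normal transform (Blom offset)
#'
#' Maps values to `qnorm((rank - 3/8) / (n + 1/4))`, with ties receiving
#' average ranks (tied inputs map to identical outputs).
#'
#' @param values Numeric vector with no missing entries, length >= 2.
#' @return Transformed vector.
#' @export
int_transform <- function(values) {
  if (anyNA(values)) stop("impute missing values before the transform")
  n <- length(values)
  if (n < 2) stop("need at least two values")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Preprocess a raw protein matrix
#'
#' In order: (1) drop proteins whose missing fraction strictly exceeds
#' `max_missing` (exactly 20% missing is kept under the default); (2) drop
#' zero-variance columns (reason `zero_variance`); (3) mean-impute each
#' remaining protein from its observed values; (4) inverse-rank normalize;
#' (5) standardize to mean 0, sd 1. Deterministic.
#'
#' @param raw Samples x proteins numeric matrix (NA = missing).
#' @param max_missing Missingness threshold (strict `>` drops).
#' @return List: `matrix` (processed, complete), `dropped` (protein/reason),
#'   `missing_fraction` (per retained protein, pre-imputation), and
#'   `state = "standardized"`.
#' @export
preprocess_proteins <- function(raw, max_missing = 0.20) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) colnames(raw) <- sprintf("prot%03d", seq_len(ncol(raw)))
  missf <- colMeans(is.na(raw))
  reason <- ifelse(missf > max_missing, "missingness", "")
  for (j in which(reason == "")) {
    v <- raw[, j][!is.na(raw[, j])]
    if (length(unique(v)) < 2) reason[j] <- "zero_variance"
  }
  keep <- reason == ""
  if (!any(keep)) stop("all proteins dropped during preprocessing")
  M <- raw[, keep, drop = FALSE]
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v <- int_transform(v)
    M[, j] <- (v - mean(v)) / stats::sd(v)
  }
  list(matrix = M,
       dropped = data.frame(protein = colnames(raw)[!keep],
                            reason = reason[!keep], stringsAsFactors = FALSE),
       missing_fraction = missf[keep], state = "standardized")
}

#' Proteome-wide logistic association scan
#'
#' Fits one logistic model per protein:
#' `outcome ~ protein + covariates [+ e4] [+ protein:e4]`, reporting the
#' per-SD log-OR with Wald se, delta-method OR CI, two-sided p, BH q over all
#' tested proteins, and a Bonferroni flag at `0.05 / m`. Separated or
#' non-converged fits are flagged and excluded from the multiplicity
#' denominator and significant sets.
#'
#' @param proteins Processed samples x proteins matrix
#'   (see [preprocess_proteins()]).
#' @param outcome Binary incident-status vector (the caller applies any
#'   incident-case definition such as excluding first-year events).
#' @param covariates Data frame/matrix of covariates (age, sex, BMI).
#' @param e4 Optional risk-haplotype copy count used for adjustment and/or
#'   interaction.
#' @param e4_adjust Add `e4` as a covariate?
#' @param e4_interaction Also add a `protein x e4` interaction term?
#' @param alpha Family-wise level for the Bonferroni flag.
#' @return Data frame `protein, beta, se, or, ci_l, ci_u, z, p, q, bonf_sig,
#'   flag [, beta_int, se_int, p_int]` plus attribute `bonferroni_threshold`.
#' @export
pwas_scan <- function(proteins, outcome, covariates, e4 = NULL,
                      e4_adjust = FALSE, e4_interaction = FALSE,
                      alpha = 0.05) {
  P <- as.matrix(proteins)
  C <- as.matrix(covariates)
  if ((e4_adjust || e4_interaction) && is.null(e4))
    stop("e4 copy counts required for adjustment/interaction")
  m <- ncol(P)
  out <- data.frame(protein = colnames(P), beta = NA_real_, se = NA_real_,
                    or = NA_real_, ci_l = NA_real_, ci_u = NA_real_,
                    z = NA_real_, p = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  if (e4_interaction) { out$beta_int <- NA_real_; out$se_int <- NA_real_; out$p_int <- NA_real_ }
  for (j in seq_len(m)) {
    X <- cbind(1, P[, j], C)
    if (e4_adjust || e4_interaction) X <- cbind(X, e4)
    if (e4_interaction) X <- cbind(X, P[, j] * e4)
    fit <- fit_logistic(X, outcome)
    if (!fit$converged) { out$flag[j] <- "nonconverged"; next }
    if (fit$separated) { out$flag[j] <- "separated"; next }
    b <- fit$beta[2]; s <- fit$se[2]
    out$beta[j] <- b; out$se[j] <- s; out$z[j] <- b / s
    out$p[j] <- p_from_z(b / s)
    ci <- or_ci(b, s)
    out$or[j] <- ci$or; out$ci_l[j] <- ci$lower; out$ci_u[j] <- ci$upper
    if (e4_interaction) {
      k <- ncol(X)
      out$beta_int[j] <- fit$beta[k]; out$se_int[j] <- fit$se[k]
      out$p_int[j] <- p_from_z(fit$beta[k] / fit$se[k])
    }
  }
  tested <- out$flag == ""
  thr <- alpha / sum(tested)
  out$q <- NA_real_
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$bonf_sig <- tested & !is.na(out$p) & out$p < thr
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Read a GMT pathway file
#'
#' @param path Path to a GMT file (name, description, members per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Pathway over-representation by Fisher's exact test
#'
#' For each pathway builds the 2x2 table of hit/non-hit x in/out-of-pathway
#' over the background and computes the one-sided (enrichment-direction)
#' hypergeometric p value, with BH q values across pathways.
#'
#' @param hits Character vector of significant proteins (subset of
#'   `background`).
#' @param background Character vector: all tested proteins.
#' @param pathways Named list of protein sets (e.g. from [read_gmt()]);
#'   members are intersected with the background.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return Data frame `pathway, n_pathway, n_overlap, odds_ratio, p, q`.
#' @export
enrich_pathways <- function(hits, background, pathways,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!all(hits %in% background)) stop("hits must be a subset of background")
  hits <- unique(hits); background <- unique(background)
  res <- do.call(rbind, lapply(names(pathways), function(nm) {
    set <- intersect(pathways[[nm]], background)
    a <- sum(hits %in% set)                       # hit & in pathway
    b <- length(hits) - a                         # hit & out
    c0 <- length(set) - a                         # non-hit & in
    d0 <- length(background) - length(set) - b    # non-hit & out
    if (length(hits) == 0) {
      return(data.frame(pathway = nm, n_pathway = length(set), n_overlap = 0L,
                        odds_ratio = NA_real_, p = 1, stringsAsFactors = FALSE))
    }
    ft <- stats::fisher.test(matrix(c(a, b, c0, d0), 2, byrow = TRUE),
                             alternative = alternative)
    data.frame(pathway = nm, n_pathway = length(set), n_overlap = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
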