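# Synthetic multi-cohort generator: genotypes with blockwise LD, a two-variant
# risk haplotype acting on a binary mediator and on the outcome, plasma-protein
# traits with cis genetic architecture, and covariates. Ground truth is kept in
# the bundle so downstream stages can be tested for parameter recovery.

#' Genetic architecture for the synthetic cohort generator
#'
#' Describes the variant panel: LD blocks (first-order autoregressive latent
#' Gaussian haplotypes thresholded to Hardy-Weinberg genotypes), allele
#' frequencies, a two-variant risk haplotype with per-copy log-odds effects on
#' a binary mediator and on the outcome, and a per-cohort allele-frequency
#' perturbation scale emulating ancestry differences.
#'
#' Each LD block is placed on its own synthetic chromosome with 1-based
#' positions spaced 5 kb apart, so clumping and lead-variant windows behave as
#' they would on a real map. Base allele frequencies are drawn once from
#' `maf_range` using `seed`, so cohorts simulated from the same architecture
#' share a variant panel.
#'
#' @param n_variants Number of biallelic variants.
#' @param n_blocks Number of LD blocks (one per synthetic chromosome).
#' @param block_r Adjacent-variant haplotype correlation within a block, in
#'   `[0, 1)`; LD decays as `block_r^distance`.
#' @param maf_range Length-2 vector of minor-allele-frequency bounds in
#'   `(0, 0.5]`.
#' @param risk_haplotype List with `variants` (two variant indices in the same
#'   block), `logor_mediator` and `logor_outcome` (per-copy log-OR of the
#'   haplotype on mediator and outcome). Set both log-ORs to 0 for a null
#'   genome.
#' @param mediator_logor Log-OR of the mediator on the outcome (the mediated
#'   path); per-copy indirect effects arise through
#'   `logor_mediator * mediator_logor`.
#' @param mediator_prev Marginal mediator prevalence.
#' @param variant_logor Optional numeric vector (length `n_variants`) of
#'   additional per-allele log-ORs on the outcome; defaults to all zero.
#' @param ancestry_fst_like Standard-deviation scale of the per-cohort logit
#'   allele-frequency perturbation (0 disables it).
#' @param seed Seed for the frequency/position draw tied to the architecture.
#' @return An object of class `gen_architecture`.
#' @export
gen_architecture <- function(n_variants = 400L,
                             n_blocks = 8L,
                             block_r = 0.8,
                             maf_range = c(0.05, 0.5),
                             risk_haplotype = list(variants = c(3L, 5L),
                                                   logor_mediator = 1.1,
                                                   logor_outcome = 0.13),
                             mediator_logor = 2.5,
                             mediator_prev = 0.02,
                             variant_logor = NULL,
                             ancestry_fst_like = 0.0,
                             seed = 1L) {
  n_variants <- as.integer(n_variants); n_blocks <- as.integer(n_blocks)
  if (n_variants < 2L || n_blocks < 1L || n_blocks > n_variants)
    stop("need n_variants >= 2 and 1 <= n_blocks <= n_variants")
  if (block_r < 0 || block_r >= 1) stop("block_r must lie in [0, 1)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair in (0, 0.5]")
  block <- sort(rep_len(seq_len(n_blocks), n_variants))
  hv <- as.integer(risk_haplotype$variants)
  if (length(hv) != 2L || any(hv < 1L) || any(hv > n_variants))
    stop("risk_haplotype variant indices out of range")
  if (block[hv[1]] != block[hv[2]])
    stop("risk-haplotype variants must lie in the same LD block")
  if (is.null(variant_logor)) variant_logor <- numeric(n_variants)
  if (length(variant_logor) != n_variants)
    stop("variant_logor must have one entry per variant")

  withr_seed <- function(s, expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(s); on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  maf <- withr_seed(seed, stats::runif(n_variants, maf_range[1], maf_range[2]))
  idx_in_block <- stats::ave(seq_len(n_variants), block, FUN = seq_along)
  map <- data.frame(
    id = sprintf("var%04d", seq_len(n_variants)),
    chrom = block,
    pos = 10000L + (idx_in_block - 1L) * 5000L,
    ea = "G", oa = "A",
    stringsAsFactors = FALSE
  )
  structure(list(
    n_variants = n_variants, n_blocks = n_blocks, block = block,
    block_r = block_r, maf_range = maf_range, maf = maf, map = map,
    risk_haplotype = list(variants = hv,
                          logor_mediator = as.numeric(risk_haplotype$logor_mediator),
                          logor_outcome = as.numeric(risk_haplotype$logor_outcome)),
    mediator_logor = mediator_logor, mediator_prev = mediator_prev,
    variant_logor = variant_logor,
    ancestry_fst_like = ancestry_fst_like, seed = as.integer(seed)
  ), class = "gen_architecture")
}

#' Protein architecture for the synthetic cohort generator
#'
#' Describes the plasma-protein panel: per-protein cis variants and effect
#' sizes on the standardized protein level, per-protein log-OR disease effects
#' on the outcome, the missing-completely-at-random rate, and a count of
#' deliberately pleiotropic variants (assigned as cis drivers of at least five
#' proteins, so the instrument pleiotropy filter has something to catch).
#'
#' Each protein is anchored to a nominal gene position at its first cis
#' variant; all its cis variants must lie within `cis_window` of that anchor
#' (inclusive), mirroring a +/-1 Mb cis definition.
#'
#' @param arch A [gen_architecture()] supplying the variant panel.
#' @param n_proteins Number of protein traits.
#' @param cis_effects List (length `n_proteins`) of data frames with columns
#'   `variant` (index) and `beta` (effect on the standardized level), or NULL
#'   to auto-assign one or two cis variants per protein with effects ~0.3.
#' @param disease_effects Per-protein log-OR on the outcome per SD of protein
#'   level (default all zero).
#' @param missing_rate Fraction of entries set missing, per protein, MCAR.
#' @param n_pleiotropic_variants Number of variants rewired to drive >= 5
#'   proteins.
#' @param cis_window Half-width (bp) of the inclusive cis window.
#' @param seed Seed for the auto-assignment draw.
#' @return An object of class `protein_architecture`.
#' @export
protein_architecture <- function(arch,
                                 n_proteins = 50L,
                                 cis_effects = NULL,
                                 disease_effects = NULL,
                                 missing_rate = 0.10,
                                 n_pleiotropic_variants = 0L,
                                 cis_window = 1e6,
                                 seed = 2L) {
  stopifnot(inherits(arch, "gen_architecture"))
  n_proteins <- as.integer(n_proteins)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed); on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  if (is.null(cis_effects)) {
    cis_effects <- vector("list", n_proteins)
    for (p in seq_len(n_proteins)) {
      b <- 1L + (p - 1L) %% arch$n_blocks       # spread proteins over blocks
      cand <- which(arch$block == b)
      k <- min(length(cand), sample(1:2, 1L))
      v <- sort(sample(cand, k))
      cis_effects[[p]] <- data.frame(variant = v,
                                     beta = stats::runif(k, 0.2, 0.4))
    }
  }
  if (length(cis_effects) != n_proteins) stop("cis_effects length mismatch")
  if (n_pleiotropic_variants > 0L) {
    # make the first cis variant of protein 1 drive five proteins
    pv <- unique(unlist(lapply(cis_effects[seq_len(min(5L, n_proteins))],
                               function(d) d$variant[1])))
    targets <- seq_len(min(5L, n_proteins))
    pl <- cis_effects[[1]]$variant[1]
    for (p in targets) {
      if (!pl %in% cis_effects[[p]]$variant)
        cis_effects[[p]] <- rbind(cis_effects[[p]],
                                  data.frame(variant = pl, beta = 0.3))
    }
  }
  if (is.null(disease_effects)) disease_effects <- numeric(n_proteins)
  if (length(disease_effects) != n_proteins) stop("disease_effects length mismatch")

  gene_pos <- data.frame(
    protein = sprintf("prot%03d", seq_len(n_proteins)),
    chrom = NA_integer_, start = NA_integer_, end = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (p in seq_len(n_proteins)) {
    ce <- cis_effects[[p]]
    v1 <- ce$variant[1]
    gene_pos$chrom[p] <- arch$map$chrom[v1]
    gene_pos$start[p] <- max(1L, arch$map$pos[v1] - 2000L)
    gene_pos$end[p] <- arch$map$pos[v1] + 2000L
    d <- abs(arch$map$pos[ce$variant] - arch$map$pos[v1])
    same <- arch$map$chrom[ce$variant] == arch$map$chrom[v1]
    if (any(!same) || any(d > cis_window))
      stop("cis variants for protein ", p, " fall outside the cis window")
  }
  structure(list(
    n_proteins = n_proteins, proteins = gene_pos$protein,
    cis_effects = cis_effects, disease_effects = disease_effects,
    missing_rate = missing_rate,
    n_pleiotropic_variants = as.integer(n_pleiotropic_variants),
    cis_window = cis_window, gene_pos = gene_pos, seed = as.integer(seed)
  ), class = "protein_architecture")
}

# intercept for a logistic model so that mean(plogis(a + eta)) = target
#' @keywords internal
solve_intercept <- function(eta, target) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}

#' Simulate one synthetic case-control cohort
#'
#' Draws haplotypes from the blockwise AR(1) latent-Gaussian LD model, forms
#' genotype dosages under Hardy-Weinberg, counts copies of the two-variant
#' risk haplotype, draws covariates (age, sex, BMI), a binary mediator, raw
#' protein levels with cis genetic effects and MCAR missingness, and finally
#' the binary outcome from a logistic model in haplotype count, mediator,
#' covariates, any per-variant effects and per-SD protein disease effects.
#' The outcome intercept is solved so the expected case fraction equals
#' `prevalence`. All generating parameters are retained in `$truth`.
#'
#' @param arch A [gen_architecture()].
#' @param parch A [protein_architecture()] or NULL for no proteomics.
#' @param n Number of individuals (>= 100).
#' @param prevalence Target outcome prevalence in (0, 0.5).
#' @param seed Integer seed; identical seed and parameters give identical
#'   output. Per-stage streams are derived from it so stages stay aligned.
#' @param cohort_id Label stored with the bundle; also offsets the ancestry
#'   frequency perturbation stream so different cohorts get different allele
#'   frequencies when `ancestry_fst_like > 0`.
#' @return A `cohort_bundle` list: `genotypes` (n x variants dosage matrix),
#'   `map`, `phenotypes`, `proteins` (raw levels with NA), `truth`.
#' @export
simulate_cohort <- function(arch, parch = NULL, n, prevalence, seed,
                            cohort_id = "cohort1") {
  stopifnot(inherits(arch, "gen_architecture"))
  n <- as.integer(n)
  if (is.na(n) || n < 100L) stop("n must be at least 100")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 0.5)
    stop("prevalence must lie strictly in (0, 0.5)")
  set.seed(as.integer(seed))
  stage_seed <- sample.int(.Machine$integer.max - 1L, 6L)

  # -- cohort allele frequencies (ancestry perturbation on the logit scale)
  p <- arch$maf
  if (arch$ancestry_fst_like > 0) {
    set.seed(stage_seed[1] + utils::head(utils::tail(as.integer(charToRaw(cohort_id)), 1), 1))
    p <- stats::plogis(stats::qlogis(p) +
                         stats::rnorm(length(p), 0, arch$ancestry_fst_like))
    p <- pmin(pmax(p, 0.005), 0.995)
  }

  # -- haplotypes: AR(1) latent Gaussian per block, thresholded at qnorm(p)
  set.seed(stage_seed[2])
  m <- arch$n_variants
  hap <- function() {
    H <- matrix(0L, n, m)
    for (b in seq_len(arch$n_blocks)) {
      idx <- which(arch$block == b)
      k <- length(idx)
      z <- matrix(stats::rnorm(n * k), n, k)
      if (arch$block_r > 0 && k > 1) {
        r <- arch$block_r
        for (j in 2:k) z[, j] <- r * z[, j - 1] + sqrt(1 - r^2) * z[, j]
      }
      thr <- stats::qnorm(p[idx])
      H[, idx] <- sweep(z, 2, thr, "<") + 0L
    }
    H
  }
  H1 <- hap(); H2 <- hap()
  G <- H1 + H2
  colnames(G) <- arch$map$id

  hv <- arch$risk_haplotype$variants
  hap_count <- (H1[, hv[1]] & H1[, hv[2]]) + (H2[, hv[1]] & H2[, hv[2]])
  hap_count <- as.integer(hap_count)

  # -- covariates
  set.seed(stage_seed[3])
  age <- round(stats::rnorm(n, 58, 8), 1)
  sex <- stats::rbinom(n, 1L, 0.46)
  bmi <- round(stats::rnorm(n, 27.4, 4.8), 2)
  age_sd <- (age - mean(age)) / stats::sd(age)

  # -- mediator (dementia-like)
  set.seed(stage_seed[4])
  eta_m <- arch$risk_haplotype$logor_mediator * hap_count + 0.6 * age_sd
  a_m <- solve_intercept(eta_m, arch$mediator_prev)
  mediator <- stats::rbinom(n, 1L, stats::plogis(a_m + eta_m))

  # -- proteins
  prot_std <- NULL; prot_raw <- NULL
  if (!is.null(parch)) {
    stopifnot(inherits(parch, "protein_architecture"))
    set.seed(stage_seed[5])
    np <- parch$n_proteins
    prot_std <- matrix(0, n, np, dimnames = list(NULL, parch$proteins))
    for (q in seq_len(np)) {
      ce <- parch$cis_effects[[q]]
      gsd <- sqrt(2 * p[ce$variant] * (1 - p[ce$variant]))
      gen <- as.matrix(G[, ce$variant, drop = FALSE]) %*%
        (ce$beta / gsd) - sum(ce$beta * 2 * p[ce$variant] / gsd)
      vres <- max(1 - sum(ce$beta^2), 0.1)
      prot_std[, q] <- gen + stats::rnorm(n, 0, sqrt(vres))
    }
    prot_raw <- sweep(prot_std * 1.5, 2, 5 + seq_len(np) * 0.01, "+") # NPX-like
    if (parch$missing_rate > 0) {
      miss <- matrix(stats::runif(n * np) < parch$missing_rate, n, np)
      prot_raw[miss] <- NA_real_
    }
  }

  # -- outcome
  set.seed(stage_seed[6])
  eta_y <- arch$risk_haplotype$logor_outcome * hap_count +
    arch$mediator_logor * mediator +
    0.35 * age_sd + 0.10 * sex
  if (any(arch$variant_logor != 0))
    eta_y <- eta_y + as.vector(G %*% arch$variant_logor)
  if (!is.null(prot_std) && any(parch$disease_effects != 0))
    eta_y <- eta_y + as.vector(prot_std %*% parch$disease_effects)
  a_y <- solve_intercept(eta_y, prevalence)
  delirium <- stats::rbinom(n, 1L, stats::plogis(a_y + eta_y))
  follow_years <- round(stats::runif(n, 1, 16), 2)
  onset_years <- ifelse(delirium == 1L, round(stats::runif(n, 0.2, 16), 2), NA)
  incident <- as.integer(delirium == 1L & !is.na(onset_years) & onset_years > 1)

  phen <- data.frame(
    sample_id = sprintf("%s_s%05d", cohort_id, seq_len(n)),
    delirium = delirium, dementia = mediator,
    age = age, sex = sex, bmi = bmi, follow_years = follow_years,
    hap_count = hap_count, onset_years = onset_years, incident = incident,
    stringsAsFactors = FALSE
  )
  rownames(G) <- phen$sample_id
  if (!is.null(prot_raw)) rownames(prot_raw) <- phen$sample_id

  bundle <- structure(list(
    genotypes = G, map = arch$map, phenotypes = phen,
    proteins = prot_raw,
    truth = list(
      cohort_id = cohort_id, n = n, prevalence = prevalence,
      seed = as.integer(seed), maf = p,
      arch = arch, parch = parch,
      intercept_mediator = a_m, intercept_outcome = a_y,
      protein_std = prot_std
    )
  ), class = "cohort_bundle")
  if (sum(delirium) == 0L) stop("simulated cohort contains no cases; increase n or prevalence")
  bundle
}

#' Write a cohort bundle to plain-text files
#'
#' Emits `genotypes.tsv` (variant_id then one dosage column per sample),
#' `variants.tsv`, `phenotypes.tsv`, `proteins.tsv` (samples x proteins, `NA`
#' for missing; omitted when the bundle carries no proteomics) and
#' `truth.yaml`, plus a `manifest.yaml` listing the files. Optionally also a
#' VCFv4.2 file with GT and DS fields.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param directory Output directory (created if needed).
#' @param vcf Also write `genotypes.vcf`?
#' @return The manifest, invisibly (named list of file paths and flags).
#' @export
write_bundle <- function(bundle, directory, vcf = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(directory, f), sep = "\t", quote = FALSE, row.names = FALSE)

  g <- data.frame(variant_id = colnames(bundle$genotypes),
                  t(bundle$genotypes), check.names = FALSE)
  tsv(g, "genotypes.tsv")
  tsv(bundle$map, "variants.tsv")
  tsv(bundle$phenotypes, "phenotypes.tsv")
  has_prot <- !is.null(bundle$proteins) && ncol(bundle$proteins) > 0
  if (has_prot) {
    pr <- data.frame(sample_id = rownames(bundle$proteins),
                     bundle$proteins, check.names = FALSE)
    tsv(pr, "proteins.tsv")
  }
  truth <- bundle$truth
  truth$arch <- unclass(truth$arch); truth$arch$map <- NULL
  if (!is.null(truth$parch)) {
    truth$parch <- unclass(truth$parch)
    truth$parch$cis_effects <- lapply(truth$parch$cis_effects, as.list)
    truth$parch$gene_pos <- as.list(truth$parch$gene_pos)
  }
  truth$protein_std <- NULL                  # large derived matrix, not truth
  yaml::write_yaml(truth, file.path(directory, "truth.yaml"), precision = 15)
  if (vcf) write_vcf(bundle, file.path(directory, "genotypes.vcf"))

  manifest <- list(
    genotypes = "genotypes.tsv", variants = "variants.tsv",
    phenotypes = "phenotypes.tsv",
    proteins = if (has_prot) "proteins.tsv" else NULL,
    proteomics_present = has_prot,
    vcf = if (vcf) "genotypes.vcf" else NULL,
    truth = "truth.yaml"
  )
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(manifest)
}

#' Write genotype dosages as VCFv4.2 with GT and DS fields
#'
#' @param bundle A `cohort_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(bundle, path) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  G <- bundle$genotypes; map <- bundle$map
  samples <- rownames(G)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=triomics_synthetic_cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage of the ALT allele">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(G))) {
    ds <- G[, j]
    gt <- ifelse(is.na(ds), "./.", gt_code[as.character(ds)])
    field <- paste(gt, ifelse(is.na(ds), ".", format(ds)), sep = ":")
    writeLines(paste(c(map$chrom[j], map$pos[j], map$id[j], map$oa[j],
                       map$ea[j], ".", "PASS", ".", "GT:DS", field),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cohort bundle written by [write_bundle()]
#'
#' @param directory Directory containing the bundle files.
#' @return A `cohort_bundle` (without the in-memory-only ground-truth
#'   standardized protein matrix).
#' @export
read_bundle <- function(directory) {
  man <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  rd <- function(f) utils::read.delim(file.path(directory, f),
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  g <- rd(man$genotypes)
  G <- t(as.matrix(g[, -1, drop = FALSE]))
  colnames(G) <- g$variant_id
  storage.mode(G) <- "integer"
  prot <- NULL
  if (isTRUE(man$proteomics_present)) {
    pr <- rd(man$proteins)
    prot <- as.matrix(pr[, -1, drop = FALSE])
    rownames(prot) <- pr$sample_id
  }
  truth <- yaml::read_yaml(file.path(directory, "truth.yaml"))
  structure(list(genotypes = G, map = rd(man$variants),
                 phenotypes = rd(man$phenotypes), proteins = prot,
                 truth = truth),
            class = "cohort_bundle")
}
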