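# Mendelian randomization: LD clumping against the generator's LD, the
# three instrument filters, the estimator battery (degenerate identities,
# sign-flip invariance, recovery) and the FDR panel.

test_that("clumping keeps independent pQTLs and removes LD partners", {
  # one block with strong LD + one independent block
  arch <- gen_architecture(n_variants = 10, n_blocks = 2, block_r = 0.95,
                           maf_range = c(0.2, 0.4),
                           risk_haplotype = list(variants = c(1L, 2L),
                                                 logor_mediator = 0,
                                                 logor_outcome = 0),
                           seed = 4)
  b <- simulate_cohort(arch, NULL, n = 3000, prevalence = 0.1, seed = 14)
  G <- b$genotypes
  r2_pair <- cor(G[, 1], G[, 2])^2
  expect_gt(r2_pair, 0.5)
  assoc <- data.frame(id = colnames(G), chrom = b$map$chrom, pos = b$map$pos,
                      p = 1, stringsAsFactors = FALSE)
  assoc$p[1:2] <- c(1e-12, 1e-10)           # LD pair in block 1
  assoc$p[7] <- 1e-9                        # independent, block 2
  cl <- ld_clump(assoc, G)
  expect_setequal(cl$index$id, c("var0001", "var0007"))
  expect_true("var0002" %in% cl$dropped$variant)
  # r2 ~ 0 pair in different blocks: both retained
  assoc2 <- assoc; assoc2$p <- 1; assoc2$p[c(1, 7)] <- 1e-9
  expect_identical(nrow(ld_clump(assoc2, G)$index), 2L)
  # strict mode retains no more than the default
  expect_lte(nrow(ld_clump(assoc, G, r2_max = 0.001)$index),
             nrow(ld_clump(assoc, G)$index))
  # absent from the LD reference: dropped with reason
  assoc3 <- rbind(assoc, data.frame(id = "ghost", chrom = 1, pos = 999,
                                    p = 1e-20))
  cl3 <- ld_clump(assoc3, G)
  expect_identical(cl3$dropped$reason[cl3$dropped$variant == "ghost"],
                   "no_ld_reference")
})

test_that("instrument filters enforce cis, strength and pleiotropy rules", {
  ex <- data.frame(id = c("v1", "v2", "v3", "v4"),
                   chrom = 1, pos = c(5e5, 1.45e6, 2e5, 3e5),
                   ea = "G", oa = "A", eaf = 0.3,
                   beta = c(0.4, 0.4, 0.05, 0.4),
                   se = c(0.03, 0.03, 0.02, 0.03),
                   stringsAsFactors = FALSE)
  out <- ex; out$beta <- 0.1; out$se <- 0.05
  gene <- list(chrom = 1, start = 2.48e6, end = 2.52e6)
  # distances from gene: v1 ~2.0 Mb (not cis), v2 1.03 Mb (not cis),
  # v3/v4 ~2.2 Mb -> need a closer gene; use inclusive boundary checks
  gene <- list(chrom = 1, start = 1.2e6, end = 1.3e6)
  # now: v1 at 0.7 Mb cis; v2 at 0.15 Mb cis; v3 cis but weak (F = 6.25);
  # v4 cis but pleiotropic when tagged with 5 proteins
  res <- build_instruments(ex, out, gene,
                           proteins_per_variant = c(v4 = 5L))
  expect_setequal(res$instruments$id, c("v1", "v2"))
  expect_identical(res$excluded$reason[res$excluded$variant == "v3"],
                   "weak_instrument")
  expect_identical(res$excluded$reason[res$excluded$variant == "v4"],
                   "pleiotropic")
  expect_equal(res$instruments$f_stat, (0.4 / 0.03)^2 * c(1, 1))
  # strictly fewer than five proteins is allowed
  res4 <- build_instruments(ex, out, gene,
                            proteins_per_variant = c(v4 = 4L))
  expect_true("v4" %in% res4$instruments$id)
  # 1.2 Mb beyond the gene fails the cis rule
  far <- ex[1, ]; far$pos <- 1.3e6 + 1.2e6
  resf <- build_instruments(far, out, gene)
  expect_identical(resf$excluded$reason, "not_cis")
  expect_equal(0.05^2 / 0.02^2, 6.25)        # the F arithmetic in the filter
})

test_that("the estimator battery honors its exact identities", {
  one <- data.frame(id = "v1", beta_exp = 0.4, se_exp = 0.03,
                    beta_out = 0.2, se_out = 0.02)
  r1 <- mr_battery(one)
  expect_identical(r1$primary, "wald_ratio")
  expect_equal(r1$estimates$beta, 0.5)
  expect_equal(r1$estimates$se, 0.02 / 0.4)
  expect_identical(r1$q$df, 0L)

  # all ratios identical: every estimator agrees, Q = 0, Egger through origin
  ins <- data.frame(id = paste0("v", 1:4),
                    beta_exp = c(0.2, 0.3, 0.4, 0.5), se_exp = 0.02,
                    beta_out = c(0.2, 0.3, 0.4, 0.5) * 0.6, se_out = 0.03)
  r <- mr_battery(ins, seed = 2)
  est <- setNames(r$estimates$beta, r$estimates$method)
  expect_equal(unname(est["ivw"]), 0.6, tolerance = 1e-10)
  expect_equal(unname(est["weighted_median"]), 0.6, tolerance = 1e-10)
  expect_equal(unname(est["max_likelihood"]), 0.6, tolerance = 1e-6)
  expect_equal(unname(est["egger"]), 0.6, tolerance = 1e-10)
  expect_equal(r$egger_intercept$beta, 0, tolerance = 1e-12)
  expect_equal(r$q$statistic, 0, tolerance = 1e-16)

  # allele recoding: flipping both effect signs leaves the estimate alone
  flip <- ins; flip$beta_exp[2] <- -flip$beta_exp[2]
  flip$beta_out[2] <- -flip$beta_out[2]
  expect_equal(mr_battery(flip, seed = 2)$estimates$beta[1],
               r$estimates$beta[1], tolerance = 1e-12)
  # Q invariant to instrument ordering
  sh <- ins[c(3, 1, 4, 2), ]
  expect_equal(mr_battery(sh, seed = 2)$q$statistic, r$q$statistic,
               tolerance = 1e-12)
  # zero exposure effect dropped with reason
  z <- rbind(ins, data.frame(id = "v5", beta_exp = 0, se_exp = 0.02,
                             beta_out = 0.1, se_out = 0.03))
  expect_identical(mr_battery(z, seed = 2)$dropped, "v5")
})

test_that("IVW recovers a generated causal effect with clean diagnostics", {
  set.seed(17)
  ok_cover <- ok_egger <- logical(0)
  for (r in 1:40) {
    k <- 8
    gamma <- runif(k, 0.2, 0.6)
    sx <- rep(0.02, k); sy <- rep(0.04, k)
    bx <- rnorm(k, gamma, sx)
    by <- rnorm(k, 0.3 * gamma, sy)          # causal effect 0.3, no pleiotropy
    ins <- data.frame(id = paste0("v", 1:k), beta_exp = bx, se_exp = sx,
                      beta_out = by, se_out = sy)
    res <- mr_battery(ins, seed = r)
    ivw <- res$estimates[res$estimates$method == "ivw", ]
    ok_cover <- c(ok_cover, abs(ivw$beta - 0.3) < 2 * ivw$se)
    ok_egger <- c(ok_egger, res$egger_intercept$p > 0.05)
  }
  expect_gte(mean(ok_cover), 0.9)
  expect_gte(mean(ok_egger), 0.85)
})

test_that("the panel applies BH over testable proteins and replication gates", {
  mk_ins <- function(seed, effect, k = 4) {
    set.seed(seed)
    gamma <- runif(k, 0.3, 0.6)
    data.frame(id = paste0("v", 1:k),
               beta_exp = rnorm(k, gamma, 0.02), se_exp = 0.02,
               beta_out = rnorm(k, effect * gamma, 0.03), se_out = 0.03)
  }
  sets <- list(A = mk_ins(1, 0.5), B = mk_ins(2, 0.4), C = mk_ins(3, 0),
               D = NULL)
  reps <- list(A = mk_ins(4, 0.5), B = mk_ins(5, -0.4), C = mk_ins(6, 0))
  tab <- mr_panel(sets, replication_sets = reps, seed = 3)
  expect_setequal(tab$protein, c("A", "B", "C"))  # D untestable, excluded
  expect_true(all(tab$fdr_sig[tab$protein %in% c("A", "B")]))
  expect_true(tab$replicated[tab$protein == "A"])
  expect_false(tab$replicated[tab$protein == "B"]) # direction flipped
  # BH arithmetic on a hand-set p vector (step-up: q2 = min(0.02, 4p3/3, p4))
  expect_equal(p.adjust(c(0.001, 0.01, 0.02, 0.8), "BH"),
               c(0.004, 0.02, 0.08 / 3, 0.8), tolerance = 1e-12)
})

test_that("a null causal effect yields uniform primary p values", {
  set.seed(23)
  ps <- replicate(200, {
    k <- 6
    gamma <- runif(k, 0.3, 0.6)
    ins <- data.frame(id = paste0("v", 1:k),
                      beta_exp = rnorm(k, gamma, 0.02), se_exp = 0.02,
                      beta_out = rnorm(k, 0, 0.03), se_out = 0.03)
    r <- mr_battery(ins, seed = 1, se_model = "fixed")
    r$estimates$p[r$estimates$method == "ivw"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # the over-dispersion guard only ever widens the interval
  set.seed(29)
  g <- runif(5, 0.3, 0.6)
  ins <- data.frame(id = paste0("v", 1:5), beta_exp = rnorm(5, g, .02),
                    se_exp = .02, beta_out = rnorm(5, 0, .03), se_out = .03)
  s_od <- mr_battery(ins, se_model = "overdispersed")$estimates
  s_fx <- mr_battery(ins, se_model = "fixed")$estimates
  expect_gte(s_od$se[s_od$method == "ivw"], s_fx$se[s_fx$method == "ivw"])
})
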