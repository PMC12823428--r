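# Meta-analysis: inverse-variance pooling against hand arithmetic, allele
# harmonization, genomic-control flooring, lead extraction, replication
# rules, liability conversion and the log-space inverse normal tail.

mk_stats <- function(id, beta, se, chrom = 1, pos = seq_along(id) * 1e5,
                     ea = "G", oa = "A", eaf = 0.3, n = 1000, n_cases = 100) {
  data.frame(id = id, chrom = chrom, pos = pos, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, z = beta / se, p = 2 * pnorm(-abs(beta / se)),
             n = n, n_cases = n_cases, stringsAsFactors = FALSE)
}

test_that("fixed-effects pooling matches hand arithmetic and its invariants", {
  s1 <- mk_stats("a", 0.2, 0.1)
  s2 <- mk_stats("a", 0.2, 0.1)
  m <- meta_fixed(list(s1, s2), gc = FALSE)
  expect_equal(m$beta, 0.2)
  expect_equal(m$se, 0.1 / sqrt(2))

  # three studies, hand-set values
  b <- c(0.15, -0.05, 0.30); se <- c(0.08, 0.12, 0.2)
  w <- 1 / se^2
  m3 <- meta_fixed(list(mk_stats("v", b[1], se[1]), mk_stats("v", b[2], se[2]),
                        mk_stats("v", b[3], se[3])), gc = FALSE)
  expect_equal(m3$beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(m3$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_identical(m3$n_studies, 3L)
  # information never decreases
  expect_lte(m3$se, min(se))
  # meta of a study with itself halves the variance
  mm <- meta_fixed(list(s1, s1), gc = FALSE)
  expect_equal(mm$se^2, s1$se^2 / 2, tolerance = 1e-12)
})

test_that("alleles are harmonized by swapping and palindromes resolved by frequency", {
  s1 <- mk_stats("a", 0.2, 0.1)
  s2 <- mk_stats("a", -0.2, 0.1, ea = "A", oa = "G", eaf = 0.7)
  m <- meta_fixed(list(s1, s2), gc = FALSE)
  expect_equal(m$beta, 0.2)                      # sign flipped back
  # palindromic with informative frequency: ok; near-0.5: dropped
  p1 <- mk_stats("p", 0.3, 0.1, ea = "A", oa = "T", eaf = 0.1)
  p2 <- mk_stats("p", 0.3, 0.1, ea = "A", oa = "T", eaf = 0.12)
  expect_equal(meta_fixed(list(p1, p2), gc = FALSE)$beta, 0.3)
  q1 <- mk_stats("q", 0.3, 0.1, ea = "A", oa = "T", eaf = 0.49)
  q2 <- mk_stats("q", 0.3, 0.1, ea = "A", oa = "T", eaf = 0.51)
  mq <- meta_fixed(list(q1, q2), gc = FALSE)
  expect_false("q" %in% mq$id)
  # single-study variants excluded unless passthrough
  s3 <- mk_stats(c("a", "b"), c(0.2, 0.1), c(0.1, 0.1))
  m1 <- meta_fixed(list(s3, s1), gc = FALSE)
  expect_false("b" %in% m1$id)
  m2 <- meta_fixed(list(s3, s1), gc = FALSE, passthrough = TRUE)
  expect_true(m2$single_study[m2$id == "b"])
})

test_that("genomic control inflates by sqrt(lambda) and floors at one", {
  set.seed(3)
  z <- rnorm(500) * 2                            # inflated: lambda ~ 4
  s_inf <- mk_stats(sprintf("v%03d", 1:500), z * 0.1, rep(0.1, 500))
  m_gc <- meta_fixed(list(s_inf, s_inf), gc = TRUE)
  m_no <- meta_fixed(list(s_inf, s_inf), gc = FALSE)
  lam <- genomic_lambda(z = z)
  expect_equal(m_gc$se / m_no$se, rep(sqrt(lam), 500), tolerance = 1e-10)
  # deflated scans are left alone (floor at 1)
  z2 <- rnorm(500) * 0.4
  s_def <- mk_stats(sprintf("v%03d", 1:500), z2 * 0.1, rep(0.1, 500))
  expect_equal(meta_fixed(list(s_def, s_def), gc = TRUE)$se,
               meta_fixed(list(s_def, s_def), gc = FALSE)$se, tolerance = 1e-12)
})

test_that("pooling two synthetic cohorts improves on single-cohort estimates", {
  set.seed(8)
  err <- matrix(NA_real_, 100, 3)
  for (r in 1:100) {
    truth <- 0.25
    se1 <- runif(1, 0.05, 0.12); se2 <- runif(1, 0.05, 0.12)
    b1 <- rnorm(1, truth, se1); b2 <- rnorm(1, truth, se2)
    m <- meta_fixed(list(mk_stats("v", b1, se1), mk_stats("v", b2, se2)),
                    gc = FALSE)
    err[r, ] <- abs(c(m$beta, b1, b2) - truth)
  }
  # pooled error beats the worse cohort nearly always, and beats each
  # cohort in mean squared error
  expect_gte(mean(err[, 1] < pmax(err[, 2], err[, 3])), 0.80)
  expect_lt(mean(err[, 1]^2), mean(err[, 2]^2))
  expect_lt(mean(err[, 1]^2), mean(err[, 3]^2))
})

test_that("greedy lead extraction honors the window and input order", {
  m <- mk_stats(c("l1", "l2"), c(0.5, 0.4), c(0.05, 0.05),
                pos = c(1e6, 1.4e6))
  leads <- lead_variants(m)
  expect_identical(leads$id, "l1")               # 400 kb apart: one lead
  m2 <- m; m2$pos <- c(1e6, 1.6e6)
  expect_identical(sort(lead_variants(m2)$id), c("l1", "l2"))
  expect_identical(nrow(lead_variants(m[integer(0), ])), 0L)

  # crafted 12-variant map with three true peaks; compare to hand expectation
  pos <- c(1.0e6, 1.2e6, 1.3e6, 2.5e6, 2.6e6, 2.9e6,
           5.0e6, 5.2e6, 5.3e6, 5.45e6, 9e6, 9.1e6)
  p <- c(1e-12, 1e-9, 1e-10, 1e-15, 1e-9, 1e-11,
         1e-20, 1e-9, 1e-13, 1e-9, 0.5, 1e-9)
  mm <- mk_stats(sprintf("x%02d", 1:12), rep(0.1, 12), rep(0.01, 12), pos = pos)
  mm$p <- p
  got <- lead_variants(mm)
  # greedy by definition: x07 (5.0), then x04 (2.5), then x01 (1.0), then
  # x10 (5.45, outside x07's window? 450 kb < 500 kb -> excluded); x12 at 9.1
  expect_identical(got$id, c("x07", "x04", "x01", "x12"))
  # invariant to input ordering
  perm <- mm[sample(12), ]
  expect_identical(lead_variants(perm)$id, got$id)
})

test_that("replication requires the Bonferroni threshold and matching direction", {
  leads <- mk_stats(sprintf("l%d", 1:5), rep(0.3, 5), rep(0.05, 5))
  rep_ok <- mk_stats(sprintf("l%d", 1:5), rep(0.2, 5), rep(0.08, 5))
  rep_ok$p <- c(0.009, 0.02, 0.0001, 0.9, 0.009)
  res <- replicate_leads(leads, rep_ok)
  expect_identical(res$pass, c(TRUE, FALSE, TRUE, FALSE, TRUE)) # thr = 0.01
  flip <- rep_ok; flip$beta <- -flip$beta
  res2 <- replicate_leads(leads, flip)
  expect_false(any(res2$pass))
  expect_true(all(res2$reason[res2$p_rep < 0.01] == "direction"))
  res3 <- replicate_leads(leads, rep_ok[1:3, ])
  expect_identical(res3$reason[4:5], c("absent", "absent"))
})

test_that("liability conversion follows the printed formula", {
  expect_equal(h2_liability(0, 0.1, 0.2)$h2_liab, 0)
  # with P = K the conversion factor collapses to K(1-K)/z^2, which always
  # exceeds 1 (K(1-K) > phi(qnorm(K))^2 over (0,1)); check both facts
  for (K in c(0.05, 0.3, 0.45)) {
    fac <- K * (1 - K) / dnorm(qnorm(K))^2
    expect_equal(h2_liability(0.4, K, K)$h2_liab, 0.4 * fac, tolerance = 1e-12)
    expect_gt(fac, 1)
  }
  # the study-scale arguments evaluate to the formula value (~0.047)
  r <- h2_liability(0.0055, 0.015, 0.018)
  z <- dnorm(qnorm(0.015))
  expect_equal(r$h2_liab,
               0.0055 * (0.015 * 0.985 / z^2) * (0.015 * 0.985 / (0.018 * 0.982)),
               tolerance = 1e-12)
  expect_equal(r$z_density, z, tolerance = 1e-10)
  expect_error(h2_liability(0.1, 1.2, 0.5), "strictly")
})

test_that("z_from_p is stable to 1e-300 and reconstructs the printed interval", {
  expect_equal(z_from_p(0.05), 1.95996, tolerance = 1e-5)
  z <- z_from_p(9.7e-177)
  expect_gt(z, 28.3); expect_lt(z, 28.4)
  se <- log(1.60) / z
  ci <- or_ci(log(1.60), se)
  expect_equal(round(ci$lower, 2), 1.55)
  expect_equal(round(ci$upper, 2), 1.65)
  # round trip across 300 orders of magnitude
  p <- 10^seq(-300, -0.005, length.out = 40)
  back <- 2 * pnorm(z_from_p(p), lower.tail = FALSE)
  expect_equal(back / p, rep(1, 40), tolerance = 1e-6)
  expect_error(z_from_p(0), "strictly")
  expect_error(z_from_p(1), "strictly")
})
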