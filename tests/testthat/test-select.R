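# Selection and prediction: split arithmetic, LASSO penalty path limits,
# stability selection, stepwise-AIC refits and discrimination metrics
# (including an exhaustive-concordance AUC oracle and the DeLong test).

sim_pred_data <- function(n, p, beta, seed, prev = 0.12) {
  set.seed(seed)
  P <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("pr%03d", 1:p)))
  D <- cbind(age = rnorm(n), sex = rbinom(n, 1, .5), bmi = rnorm(n))
  eta <- as.vector(P %*% beta)
  a <- uniroot(function(a) mean(plogis(a + eta)) - prev, c(-20, 10))$root
  y <- rbinom(n, 1, plogis(a + eta))
  e4 <- rbinom(n, 2, 0.15)
  list(P = P, D = D, y = y, e4 = e4)
}

test_that("the train/test split is seeded, sized and case-guarded", {
  sp <- split_cohort(10, 0.2, seed = 3)
  expect_length(sp$test, 2)
  expect_length(sp$train, 8)
  expect_identical(split_cohort(10, 0.2, seed = 3), sp)
  expect_false(identical(split_cohort(10, 0.2, seed = 4)$test, sp$test))
  expect_error(split_cohort(3, 0.01), "degenerate")
  y <- c(1, rep(0, 99))
  expect_error(split_cohort(100, 0.2, seed = 1, cases = y), "two cases")
})

test_that("the penalty path obeys its limits and the one-se rule", {
  d <- sim_pred_data(400, 12, c(1.2, rep(0, 11)), seed = 5, prev = 0.3)
  cv <- lasso_cv(d$P, d$D, d$y, seed = 2)
  expect_gte(cv$lambda.1se, cv$lambda.min)
  k <- which(cv$path$lambda == cv$lambda.min)
  k1 <- which(cv$path$lambda == cv$lambda.1se)
  expect_lte(cv$path$cvm[k1], cv$path$cvm[k] + cv$path$cvsd[k] + 1e-12)
  expect_identical(nrow(cv$path), 100L)
  expect_equal(range(cv$path$lambda), c(1e-6, 0.07), tolerance = 1e-9)

  # a penalty above the critical value shrinks every protein to zero
  fit_hi <- glmnet::glmnet(cbind(d$D, d$P), d$y, family = "binomial",
                           lambda = 0.5,
                           penalty.factor = c(rep(0, 3), rep(1, 12)),
                           standardize = FALSE)
  b_hi <- as.matrix(coef(fit_hi))[colnames(d$P), 1]
  expect_true(all(b_hi == 0))

  # penalty -> 0 approaches the unpenalized fit on a small toy
  d2 <- sim_pred_data(120, 4, c(0.8, 0.4, 0, 0), seed = 6, prev = 0.4)
  X <- cbind(1, d2$D, d2$P)
  ref <- oracle_logistic(X, d2$y)
  fit_lo <- glmnet::glmnet(cbind(d2$D, d2$P), d2$y, family = "binomial",
                           lambda = c(0.05, 1e-3, 1e-8),
                           penalty.factor = c(rep(0, 3), rep(1, 4)),
                           standardize = FALSE, thresh = 1e-14)
  b_lo <- as.matrix(coef(fit_lo, s = 1e-8))[, 1]
  expect_equal(unname(b_lo[colnames(d2$P)]),
               ref$beta[5:8], tolerance = 1e-3)
})

test_that("stability selection separates signal from noise and is inclusive at the threshold", {
  d <- sim_pred_data(1200, 40, c(2, rep(0, 39)), seed = 9, prev = 0.2)
  cv <- lasso_cv(d$P, d$D, d$y, seed = 3)
  st <- stability_select(d$P, d$D, d$y, cv$lambda.1se, n_iter = 50, seed = 4)
  expect_equal(unname(st$frequency["pr001"]), 1)
  expect_gte(mean(st$frequency[-1] < 0.5), 0.95)
  expect_true("pr001" %in% st$selected)
  # the frequency threshold is inclusive ("at least half")
  st_edge <- stability_select(d$P, d$D, d$y, cv$lambda.1se, n_iter = 50,
                              threshold = max(st$frequency), seed = 4)
  expect_true(all(st_edge$frequency[st_edge$selected] >= max(st$frequency)))
  expect_true("pr001" %in% st_edge$selected)
  # determinism
  st2 <- stability_select(d$P, d$D, d$y, cv$lambda.1se, n_iter = 50, seed = 4)
  expect_identical(st$frequency, st2$frequency)
  # refuse resampling when controls are scarcer than cases
  yb <- c(rep(1, 60), rep(0, 30))
  expect_error(stability_select(d$P[1:90, ], d$D[1:90, ], yb, 0.01, seed = 1),
               "fewer controls")
})

test_that("stepwise refits force demographics, prune null proteins and lower AIC", {
  d <- sim_pred_data(3000, 6, c(1.0, 0.8, 0, 0, 0, 0), seed = 11, prev = 0.25)
  sel <- c("pr001", "pr002", "pr005")           # pr005 carries no effect
  mods <- refit_models(d$y, d$D, d$P, d$e4, sel)
  expect_named(mods, c("basic", "proteomic", "proteomic_basic",
                       "apoe_proteomic_basic"))
  expect_identical(names(mods$basic$beta), c("(Intercept)", "age", "sex", "bmi"))
  m3 <- mods$proteomic_basic
  expect_true(all(c("pr001", "pr002") %in% m3$proteins))
  expect_false("pr005" %in% m3$proteins)        # null protein eliminated
  expect_true("e4_count" %in% names(mods$apoe_proteomic_basic$beta))
  # empty selection skips protein models with a message
  expect_message(m0 <- refit_models(d$y, d$D, d$P, d$e4, character(0)),
                 "skipped")
  expect_named(m0, "basic")
})

test_that("AUC matches exhaustive pairwise concordance and its invariances", {
  # 8-point hand example
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2, 0.6, 0.5)
  labels <- c(0, 0, 1, 1, 0, 0, 1, 1)
  conc <- 0; n1 <- sum(labels); n0 <- sum(1 - labels)
  for (i in which(labels == 1)) for (j in which(labels == 0))
    conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_equal(roc_auc(scores, labels), conc / (n1 * n0))
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(labels, scores, quiet = TRUE,
                                    direction = "<")))
  # monotone transform invariance
  expect_equal(roc_auc(exp(3 * scores), labels), roc_auc(scores, labels))
  # perfect separation
  expect_equal(roc_auc(labels * 2, labels), 1)
  expect_equal(pr_auc(labels * 2, labels), 1)
  # constant scores: AUC 1/2, PR AUC = prevalence
  expect_equal(roc_auc(rep(1, 8), labels), 0.5)
  expect_equal(pr_auc(rep(1, 8), labels), mean(labels), tolerance = 1e-10)
})

test_that("model evaluation orders the nested models and handles ties", {
  d <- sim_pred_data(6000, 5, c(0.9, 0.7, 0.5, 0, 0), seed = 13, prev = 0.15)
  sp <- split_cohort(6000, 0.2, seed = 8, cases = d$y)
  tr <- sp$train; te <- sp$test
  mods <- refit_models(d$y[tr], d$D[tr, ], d$P[tr, ], d$e4[tr],
                       c("pr001", "pr002", "pr003"))
  ev <- evaluate_models(mods, d$y[te], d$D[te, ], d$P[te, ], d$e4[te])
  expect_true(all(ev$metrics$auc >= 0 & ev$metrics$auc <= 1))
  # proteins carry all the signal here: proteomic models beat basic
  expect_gt(ev$metrics$auc[ev$metrics$model == "proteomic_basic"],
            ev$metrics$auc[ev$metrics$model == "basic"])
  expect_gt(ev$metrics$pr_auc[ev$metrics$model == "proteomic_basic"],
            ev$metrics$pr_auc[ev$metrics$model == "basic"])
  expect_true(all(is.finite(ev$pairwise$delong_p)))
  # identical score vectors: delta 0, p 1
  mods2 <- mods[c("basic", "basic")]
  names(mods2) <- c("m1", "m2")
  ev2 <- evaluate_models(structure(mods2, class = "refit_models"),
                         d$y[te], d$D[te, ], d$P[te, ], d$e4[te])
  expect_equal(ev2$pairwise$delta_auc, 0)
  expect_equal(ev2$pairwise$delong_p, 1)
  expect_error(evaluate_models(mods, rep(0, 10), d$D[1:10, ], d$P[1:10, ],
                               d$e4[1:10]), "single class")
})

test_that("the printed case bookkeeping follows from the split arithmetic", {
  expect_identical(541L - 436L, 105L)
  sp <- split_cohort(2000, 0.2, seed = 2)
  expect_length(sp$test, 400)
  expect_length(intersect(sp$train, sp$test), 0)
})
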