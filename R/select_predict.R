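# L1-penalized protein selection with cross-validated penalty, balanced
# case-control subsample stability selection, backward stepwise-AIC refits of
# four nested prediction models, and test-set discrimination (ROC AUC, PR
# AUC, paired DeLong comparisons).

#' Random train/test split
#'
#' Simple random, non-stratified split of row indices, reproducible by seed.
#'
#' @param n Number of rows (or a data frame, in which case its row count).
#' @param test_fraction Fraction assigned to the test set.
#' @param seed Seed.
#' @param cases Optional binary vector; both partitions are required to
#'   contain at least one case.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(n, test_fraction = 0.20, seed = 1L, cases = NULL) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  n <- as.integer(n)
  n_test <- round(test_fraction * n)
  if (n_test < 1L || n_test >= n) stop("degenerate split sizes")
  set.seed(as.integer(seed))
  test <- sort(sample.int(n, n_test))
  train <- setdiff(seq_len(n), test)
  if (!is.null(cases)) {
    if (sum(cases) < 2L) stop("need at least two cases to split")
    if (sum(cases[test]) < 1L || sum(cases[train]) < 1L)
      stop("split left a partition without cases; change seed")
  }
  list(train = train, test = test)
}

#' Cross-validated LASSO penalty path for protein selection
#'
#' Fits an L1-penalized logistic model over a log-spaced grid of 100
#' penalties in [1e-6, 0.07] (by default) with 10-fold cross-validated
#' binomial deviance, demographics unpenalized. Fold labels are seeded and
#' shared across the grid. `lambda.1se` is the largest penalty whose CV loss
#' is within one standard error of the minimum.
#'
#' @param proteins Standardized samples x proteins matrix (training set).
#' @param demographics Matrix/data frame of unpenalized covariates.
#' @param y Binary outcome.
#' @param grid Penalty grid (decreasing after sorting); default 100 log-
#'   spaced values in [1e-6, 0.07].
#' @param folds Number of CV folds.
#' @param seed Seed for fold assignment.
#' @param type.measure CV loss (`"deviance"` default, `"class"` optional).
#' @return A `penalty_path` list: `path` (lambda, cvm, cvsd), `lambda.min`,
#'   `lambda.1se`, `fit` (the underlying cv.glmnet object), `predictors`.
#' @export
lasso_cv <- function(proteins, demographics, y, grid = NULL, folds = 10L,
                     seed = 1L, type.measure = c("deviance", "class")) {
  type.measure <- match.arg(type.measure)
  if (is.null(grid)) grid <- exp(seq(log(0.07), log(1e-6), length.out = 100))
  grid <- sort(grid, decreasing = TRUE)
  P <- as.matrix(proteins); D <- as.matrix(demographics)
  X <- cbind(D, P)
  pf <- c(rep(0, ncol(D)), rep(1, ncol(P)))
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(folds), nrow(X)))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", lambda = grid,
                          penalty.factor = pf, foldid = foldid,
                          standardize = FALSE, type.measure = type.measure,
                          thresh = 1e-7)
  structure(list(
    path = data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd),
    lambda.min = cv$lambda.min, lambda.1se = cv$lambda.1se,
    fit = cv, predictors = colnames(X), n_unpenalized = ncol(D)
  ), class = "penalty_path")
}

#' Nonzero protein coefficients of a LASSO fit at one penalty
#' @keywords internal
lasso_selected <- function(X, y, pf, penalty, protein_names) {
  fit <- glmnet::glmnet(X, y, family = "binomial",
                        lambda = c(penalty * 4, penalty),  # short path for warm start
                        penalty.factor = pf, standardize = FALSE, thresh = 1e-7)
  b <- as.matrix(stats::coef(fit, s = penalty))[, 1]
  names(which(b[protein_names] != 0))
}

#' Balanced-subsample stability selection
#'
#' Repeats, `n_iter` times: take all cases plus an equal-size random control
#' subsample (without replacement), fit the LASSO at the fixed `penalty`
#' (typically `lambda.1se` tuned on the full training set), and record which
#' proteins get nonzero coefficients. A protein is stability-selected when
#' its selection frequency is at least `threshold` (frequency exactly 0.5
#' counts as selected under the default).
#'
#' @param proteins Standardized samples x proteins matrix (training set).
#' @param demographics Unpenalized covariates.
#' @param y Binary outcome; controls must outnumber cases.
#' @param penalty Fixed LASSO penalty.
#' @param n_iter Subsampling iterations (default 100).
#' @param threshold Selection-frequency threshold (default 0.5, inclusive).
#' @param seed Seed.
#' @return A `stability_result`: `frequency` (named, in [0,1]), `selected`
#'   (character), `n_iter`, `threshold`.
#' @export
stability_select <- function(proteins, demographics, y, penalty,
                             n_iter = 100L, threshold = 0.5, seed = 1L) {
  P <- as.matrix(proteins); D <- as.matrix(demographics)
  if (is.null(colnames(P))) colnames(P) <- sprintf("prot%03d", seq_len(ncol(P)))
  cases <- which(y == 1); controls <- which(y == 0)
  if (length(cases) < 20L) stop("need at least 20 training cases")
  if (length(controls) < length(cases))
    stop("fewer controls than cases; refusing to sample with replacement")
  pf <- c(rep(0, ncol(D)), rep(1, ncol(P)))
  hits <- integer(ncol(P)); names(hits) <- colnames(P)
  set.seed(as.integer(seed))
  for (it in seq_len(n_iter)) {
    i <- c(cases, sample(controls, length(cases)))
    sel <- lasso_selected(cbind(D[i, , drop = FALSE], P[i, , drop = FALSE]),
                          y[i], pf, penalty, colnames(P))
    hits[sel] <- hits[sel] + 1L
  }
  freq <- hits / n_iter
  structure(list(frequency = freq,
                 selected = names(freq)[freq >= threshold],
                 n_iter = n_iter, threshold = threshold),
            class = "stability_result")
}

# logistic fit keeping names; returns beta/aic
#' @keywords internal
glm_named <- function(X, y) {
  fit <- fit_logistic(X, y)
  b <- fit$beta; names(b) <- colnames(X)
  list(beta = b, aic = fit$aic, se = fit$se)
}

# backward AIC elimination over protein columns only (forced stays)
#' @keywords internal
backward_aic <- function(forced, prot, y) {
  current <- sort(colnames(prot))
  path <- character(0)
  repeat {
    X <- cbind(forced, prot[, current, drop = FALSE])
    aic_cur <- glm_named(X, y)$aic
    if (!length(current)) break
    cand_aic <- vapply(current, function(pn) {
      rest <- setdiff(current, pn)
      glm_named(cbind(forced, prot[, rest, drop = FALSE]), y)$aic
    }, numeric(1))
    best <- min(cand_aic)
    if (best < aic_cur) {                 # drop lowers AIC: proceed
      drop <- sort(names(cand_aic)[cand_aic == best])[1]  # tie: alphabetical
      current <- setdiff(current, drop)
      path <- c(path, drop)
    } else break
  }
  list(proteins = current, dropped = path)
}

#' Refit the four nested prediction models with stepwise-AIC protein pruning
#'
#' Fits (1) a basic model (demographics only), (2) a proteomic model
#' (stability-selected proteins only), (3) proteomic + basic, and (4)
#' haplotype + proteomic + basic. For models 2-4, proteins are pruned by
#' backward elimination: at each step the removal that most lowers AIC is
#' applied (ties broken alphabetically) until no removal improves AIC;
#' demographics and the haplotype count are never removed.
#'
#' @param y Binary training outcome.
#' @param demographics Matrix/data frame (age, sex, BMI).
#' @param proteins Standardized protein matrix (training set).
#' @param e4 Risk-haplotype copy count.
#' @param selected Character vector of stability-selected proteins; when
#'   empty, models 2-4 are skipped with a message.
#' @return A `refit_models` list of per-model lists
#'   (`name, beta, proteins, uses_demog, uses_e4`).
#' @export
refit_models <- function(y, demographics, proteins, e4, selected) {
  D <- as.matrix(demographics)
  Int <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  models <- list()
  models$basic <- list(name = "basic",
                       beta = glm_named(cbind(Int, D), y)$beta,
                       proteins = character(0), uses_demog = TRUE,
                       uses_e4 = FALSE)
  if (!length(selected)) {
    message("no stability-selected proteins; protein models skipped")
    return(structure(models, class = "refit_models"))
  }
  P <- as.matrix(proteins)[, selected, drop = FALSE]
  specs <- list(
    proteomic = list(forced = Int, e4 = FALSE, demog = FALSE),
    proteomic_basic = list(forced = cbind(Int, D), e4 = FALSE, demog = TRUE),
    apoe_proteomic_basic = list(forced = cbind(Int, D, e4_count = e4),
                                e4 = TRUE, demog = TRUE)
  )
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    bw <- backward_aic(sp$forced, P, y)
    X <- cbind(sp$forced, P[, bw$proteins, drop = FALSE])
    models[[nm]] <- list(name = nm, beta = glm_named(X, y)$beta,
                         proteins = bw$proteins, dropped = bw$dropped,
                         uses_demog = sp$demog, uses_e4 = sp$e4)
  }
  structure(models, class = "refit_models")
}

# linear predictor of one refit model on new data components
#' @keywords internal
model_scores <- function(model, demographics, proteins, e4) {
  n <- if (model$uses_demog) nrow(as.matrix(demographics)) else
    if (length(model$proteins)) nrow(as.matrix(proteins)) else length(e4)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (model$uses_demog) X <- cbind(X, as.matrix(demographics))
  if (model$uses_e4) X <- cbind(X, e4_count = e4)
  if (length(model$proteins))
    X <- cbind(X, as.matrix(proteins)[, model$proteins, drop = FALSE])
  as.vector(X %*% model$beta[colnames(X)])
}

#' ROC AUC by the rank (concordance) statistic
#'
#' @param scores Numeric predictions.
#' @param labels Binary 0/1 outcomes (both classes present).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Precision and recall are evaluated at each distinct score threshold
#' (descending); the area is the trapezoid over recall, anchored at recall 0
#' with the first attainable precision. A constant score yields the case
#' prevalence; a perfectly separating score yields 1.
#'
#' @param scores Numeric predictions.
#' @param labels Binary 0/1 outcomes (both classes present).
#' @return PR AUC in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || sum(labels == 0) == 0) stop("both classes required")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)    # keep final row per threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp); rec <- tp / n1
  rec0 <- c(0, rec); prec0 <- c(prec[1], prec)
  sum(diff(rec0) * (utils::head(prec0, -1) + utils::tail(prec0, -1)) / 2)
}

#' Test-set discrimination of the refit models
#'
#' Computes ROC AUC (rank statistic) and PR AUC per model and all pairwise
#' AUC differences with two-sided paired DeLong p values.
#'
#' @param models A `refit_models` object.
#' @param y Test outcome (binary, both classes present).
#' @param demographics,proteins,e4 Test-set components matching the training
#'   columns.
#' @return A `prediction_eval` list: `metrics` (model, auc, pr_auc),
#'   `pairwise` (model1, model2, delta_auc, delong_p), `scores` matrix.
#' @export
evaluate_models <- function(models, y, demographics, proteins, e4) {
  if (length(unique(y)) < 2) stop("test set contains a single class")
  S <- vapply(models, model_scores, numeric(length(y)),
              demographics = demographics, proteins = proteins, e4 = e4)
  metrics <- data.frame(
    model = names(models),
    auc = apply(S, 2, roc_auc, labels = y),
    pr_auc = apply(S, 2, pr_auc, labels = y),
    stringsAsFactors = FALSE)
  combs <- utils::combn(names(models), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    dp <- if (isTRUE(all.equal(S[, a], S[, b]))) 1 else {
      ra <- pROC::roc(y, S[, a], quiet = TRUE, direction = "<")
      rb <- pROC::roc(y, S[, b], quiet = TRUE, direction = "<")
      as.numeric(pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value)
    }
    data.frame(model1 = a, model2 = b,
               delta_auc = metrics$auc[metrics$model == b] -
                 metrics$auc[metrics$model == a],
               delong_p = dp, stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, pairwise = pairwise, scores = S),
            class = "prediction_eval")
}
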