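#' Assemble the model feature matrix
#'
#' Builds the individuals-by-features matrix for the risk models: variant
#' dosages flipped to the risk direction (dosage `d` becomes `2 - d` when
#' the supplied meta-analysis beta is negative, so higher dosage always
#' means higher risk), restricted to the requested submodel, with optional
#' covariates (sex, four genotype PCs, cohort dummies).
#'
#' @param cohort A `cohort_data` object.
#' @param betas Optional named log-OR vector used for risk-direction
#'   flipping (no flipping when absent).
#' @param submodel `"ALL"`, `"MHC_ONLY"` or `"NON_MHC"`.
#' @param with_covars Add sex + PC1-4 + cohort dummies.
#' @return List: `X` (numeric matrix), `groups` (feature group labels,
#'   `MHC`/`NON_MHC`/`COVAR`), `flipped` (ids whose dosage was flipped).
#' @export
assemble_features <- function(cohort, betas = NULL,
                              submodel = c("ALL", "MHC_ONLY", "NON_MHC"),
                              with_covars = FALSE) {
  submodel <- match.arg(submodel)
  panel <- cohort$panel
  keep <- switch(submodel,
                 ALL = rep(TRUE, nrow(panel)),
                 MHC_ONLY = panel$group == "MHC",
                 NON_MHC = panel$group == "NON_MHC")
  ids <- panel$id[keep]
  X <- cohort$dosage[, ids, drop = FALSE]
  storage.mode(X) <- "double"
  flipped <- character()
  if (!is.null(betas)) {
    flip <- intersect(ids, names(betas)[betas < 0])
    X[, flip] <- 2 - X[, flip]
    flipped <- flip
  }
  groups <- panel$group[keep]
  if (with_covars) {
    s <- cohort$samples
    C <- cbind(sex = s$sex, PC1 = s$PC1, PC2 = s$PC2, PC3 = s$PC3,
               PC4 = s$PC4)
    coh <- sort(unique(s$cohort))
    D <- sapply(coh, function(cc) as.numeric(s$cohort == cc))
    colnames(D) <- paste0("cohort_", coh)
    X <- cbind(X, C, D)
    groups <- c(groups, rep("COVAR", ncol(C) + ncol(D)))
  }
  names(groups) <- colnames(X)
  list(X = X, groups = groups, flipped = flipped, submodel = submodel)
}

# Stratified k-fold assignment: cases and controls split separately so
# every fold holds both classes.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  if (any(tabulate(fold[y == 1], k) == 0) || any(tabulate(fold[y == 0], k) == 0))
    stop_named("a fold lost a class; reduce k or increase n")
  fold
}

#' Train the gradient-boosted risk model with out-of-fold scoring
#'
#' Stratified k-fold cross-validation: for each fold the model is fit on
#' the other folds and the held-out individuals are scored, so every
#' individual receives exactly one out-of-fold probability ("score").
#' A representative model fit on all individuals is retained for
#' validation-style use. Defaults follow the tuned configuration:
#' 254 trees, depth 5, learning rate 0.12, with heavy leaf regularization
#' (L2 leaf weight `lambda`, minimum leaf size as a fraction of the
#' training rows) so the ensemble generalizes like the strongly
#' regularized boosting frameworks this configuration was tuned in, rather
#' than memorizing genotype noise.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param k Number of folds (default 10).
#' @param params List with `trees`, `depth`, `lr`, and optionally
#'   `lambda` (L2 leaf regularization, default 30) and `min_child_frac`
#'   (minimum hessian weight per leaf as a fraction of training rows,
#'   default 0.01).
#' @param seed Integer seed (fold split and training are deterministic
#'   given the seed).
#' @return A `model_bundle`: `models` (per fold), `full_model`, `fold`,
#'   `oof` (out-of-fold scores), `params`, `features`.
#' @export
train_gbdt_cv <- function(X, y, k = 10L,
                          params = list(trees = 254L, depth = 5L, lr = 0.12),
                          seed = 1L) {
  stopifnot(nrow(X) == length(y))
  params$lambda <- params$lambda %||% 30
  params$min_child_frac <- params$min_child_frac %||% 0.01
  fold <- stratified_folds(y, k, child_seed(seed, "folds"))
  n_train <- round(length(y) * (k - 1) / k)
  xparams <- list(objective = "binary:logistic", max_depth = params$depth,
                  eta = params$lr, reg_lambda = params$lambda,
                  min_child_weight = max(1, round(params$min_child_frac *
                                                    n_train)),
                  nthread = 1L, seed = child_seed(seed, "gbdt"))
  oof <- numeric(length(y))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    models[[f]] <- xgboost::xgb.train(params = xparams, data = dtr,
                                      nrounds = params$trees, verbose = 0)
    oof[!tr] <- predict(models[[f]],
                        xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
  }
  dall <- xgboost::xgb.DMatrix(X, label = y)
  full <- xgboost::xgb.train(params = xparams, data = dall,
                             nrounds = params$trees, verbose = 0)
  structure(list(models = models, full_model = full, fold = fold, oof = oof,
                 params = params, features = colnames(X), k = k,
                 model_type = "gbdt"),
            class = "model_bundle")
}

#' Train the L2-regularized logistic baseline with out-of-fold scoring
#'
#' Ridge logistic regression at the strong regularization used for the
#' linear comparison model (`C = 0.001` in scikit-learn convention, mapped
#' to `lambda = 1 / (C * n_train)`), with the same stratified k-fold
#' protocol as the tree model.
#'
#' @inheritParams train_gbdt_cv
#' @param l2_c Inverse regularization strength `C`.
#' @return A `model_bundle` with per-fold coefficient vectors.
#' @export
train_logreg_cv <- function(X, y, l2_c = 0.001, k = 10L, seed = 1L) {
  fold <- stratified_folds(y, k, child_seed(seed, "folds"))
  oof <- numeric(length(y))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    lam <- 1 / (l2_c * sum(tr))
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lam, standardize = FALSE)
    models[[f]] <- fit
    oof[!tr] <- as.numeric(predict(fit, X[!tr, , drop = FALSE],
                                   type = "response"))
  }
  lam <- 1 / (l2_c * length(y))
  full <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lam,
                         standardize = FALSE)
  structure(list(models = models, full_model = full, fold = fold, oof = oof,
                 params = list(l2_c = l2_c), features = colnames(X), k = k,
                 model_type = "logreg"),
            class = "model_bundle")
}

#' Additive genetic risk score
#'
#' Weighted dosage sum with optional diplotype-class terms, the classical
#' additive-GRS engine used as a linear baseline.
#'
#' @param X Dosage/feature matrix.
#' @param weights Named weight vector over columns of `X`.
#' @param class_weights Optional named vector of extra terms per MHC
#'   diplotype class.
#' @param mhc_class Factor of diplotype classes (required with
#'   `class_weights`).
#' @return Numeric score per individual.
#' @export
additive_grs <- function(X, weights, class_weights = NULL, mhc_class = NULL) {
  unknown <- setdiff(names(weights), colnames(X))
  if (length(unknown))
    stop_named("weights reference unknown features: %s",
               paste(unknown, collapse = ", "))
  s <- as.vector(X[, names(weights), drop = FALSE] %*% weights)
  if (!is.null(class_weights)) {
    stopifnot(!is.null(mhc_class))
    extra <- class_weights[as.character(mhc_class)]
    extra[is.na(extra)] <- 0
    s <- s + extra
  }
  unname(s)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator; ties contribute one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Step-wise integral of the precision-recall curve,
#' `AP = sum_k (R_k - R_(k-1)) P_k` over descending score thresholds.
#'
#' @inheritParams auc
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(sum(labels == 1) > 0)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate only at distinct thresholds (last index of each tied run)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

# Placement values for the fast DeLong machinery.
delong_placements <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  n1 <- length(cases); n0 <- length(controls)
  all_r <- rank(c(cases, controls))
  r1 <- rank(cases); r0 <- rank(controls)
  v10 <- (all_r[seq_len(n1)] - r1) / n0
  v01 <- 1 - (all_r[n1 + seq_len(n0)] - r0) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two scores on the same individuals,
#' using per-sample placement values to estimate the variance of the AUC
#' difference; two-sided normal p-value.
#'
#' @param scores_a,scores_b Two score vectors on the same individuals.
#' @param labels 0/1 labels.
#' @return List: `auc_a`, `auc_b`, `delta`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.numeric(labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  v <- stats::var(pa$v10 - pb$v10) / n1 + stats::var(pa$v01 - pb$v01) / n0
  delta <- pa$auc - pb$auc
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z, p = p)
}

#' Two-sided McNemar test from discordant counts
#'
#' Exact binomial when the discordant total is 15 or fewer, otherwise the
#' continuity-corrected chi-square.
#'
#' @param n_ab Count where classifier A errs and B does not.
#' @param n_ba Count where classifier B errs and A does not.
#' @return List: `p`, `method`.
#' @export
mcnemar_test <- function(n_ab, n_ba) {
  m <- n_ab + n_ba
  if (m == 0) return(list(p = 1, method = "degenerate"))
  if (m <= 15) {
    p <- min(1, 2 * stats::pbinom(min(n_ab, n_ba), m, 0.5))
    list(p = p, method = "exact")
  } else {
    stat <- (abs(n_ab - n_ba) - 1)^2 / m
    list(p = stats::pchisq(stat, 1, lower.tail = FALSE), method = "chisq")
  }
}

#' Stratified McNemar comparison of two classifiers
#'
#' Within each stratum (e.g. DR3/DR4 diplotype class), compares
#' false-negative discordance among cases and false-positive discordance
#' among controls; the rate difference is reported as baseline minus model.
#'
#' @param pred_a Baseline binary predictions.
#' @param pred_b Model binary predictions.
#' @param labels 0/1 labels.
#' @param strata Factor of strata.
#' @return Data frame with one row per stratum x error type: `stratum`,
#'   `type` (`FN`/`FP`), `rate_a`, `rate_b`, `diff`, `n_ab`, `n_ba`, `p`.
#' @export
mcnemar_strata <- function(pred_a, pred_b, labels, strata) {
  labels <- as.numeric(labels)
  rows <- list()
  for (s in levels(factor(strata))) {
    i <- strata == s
    for (type in c("FN", "FP")) {
      j <- i & (labels == if (type == "FN") 1 else 0)
      if (!any(j)) next
      wrong_a <- if (type == "FN") pred_a[j] == 0 else pred_a[j] == 1
      wrong_b <- if (type == "FN") pred_b[j] == 0 else pred_b[j] == 1
      n_ab <- sum(wrong_a & !wrong_b)
      n_ba <- sum(!wrong_a & wrong_b)
      tst <- mcnemar_test(n_ab, n_ba)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, type = type, rate_a = mean(wrong_a),
        rate_b = mean(wrong_b), diff = mean(wrong_a) - mean(wrong_b),
        n_ab = n_ab, n_ba = n_ba, p = tst$p, method = tst$method,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Youden index
#'
#' `J = sensitivity + specificity - 1`. Inputs may be fractions or
#' percentages (values above 1 are interpreted as percent).
#'
#' @param sens,spec Sensitivity and specificity.
#' @return Youden's J on the fraction scale.
#' @export
youden_index <- function(sens, spec) {
  if (any(c(sens, spec) > 1)) { sens <- sens / 100; spec <- spec / 100 }
  sens + spec - 1
}

#' Diagnostic score scale with Youden indices
#'
#' Thresholds are placed at nearest-rank centiles of the case score
#' distribution; at each threshold an individual is called positive when
#' the score is at or above it. Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP).
#'
#' @param scores Model scores.
#' @param labels 0/1 labels.
#' @param centiles Case-score centiles for the thresholds.
#' @return Data frame: `threshold`, `case_centile`, `control_centile`,
#'   `sensitivity` (%), `specificity` (%), `youden`.
#' @export
youden_scale <- function(scores, labels,
                         centiles = c(seq(5, 50, by = 5), 75, 95)) {
  labels <- as.numeric(labels)
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  stopifnot(length(cases) > 0, length(controls) > 0)
  rows <- lapply(centiles, function(cc) {
    thr <- as.numeric(stats::quantile(cases, cc / 100, type = 1))
    sens <- mean(cases >= thr)
    spec <- mean(controls < thr)
    data.frame(threshold = thr, case_centile = cc,
               control_centile = 100 * mean(controls < thr),
               sensitivity = 100 * sens, specificity = 100 * spec,
               youden = youden_index(sens, spec))
  })
  do.call(rbind, rows)
}
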