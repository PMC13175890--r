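# Small, fast model settings for structural tests.
tiny_params <- list(trees = 30L, depth = 3L, lr = 0.3, lambda = 1,
                    min_child_frac = 0)

test_that("assemble_features partitions submodels and flips risk direction", {
  p <- variant_panel(10, n_mhc = 4)
  eff <- effect_spec(additive = c(var005 = 0.4), intercept = qlogis(0.3))
  co <- simulate_cohort(300, p, eff, mhc = mhc_spec(), seed = 41)
  all_f <- assemble_features(co)
  mhc_f <- assemble_features(co, submodel = "MHC_ONLY")
  non_f <- assemble_features(co, submodel = "NON_MHC")
  expect_setequal(c(colnames(mhc_f$X), colnames(non_f$X)), colnames(all_f$X))
  expect_true(all(mhc_f$groups == "MHC"))
  expect_true(all(non_f$groups == "NON_MHC"))

  cov_f <- assemble_features(co, with_covars = TRUE)
  extra <- setdiff(colnames(cov_f$X), colnames(all_f$X))
  expect_setequal(extra, c("sex", "PC1", "PC2", "PC3", "PC4",
                           "cohort_1", "cohort_2"))
  expect_true(all(cov_f$groups[extra] == "COVAR"))

  flip <- assemble_features(co, betas = c(var006 = -0.2))
  expect_equal(flip$flipped, "var006")
  expect_equal(flip$X[, "var006"], 2 - all_f$X[, "var006"])
})

test_that("out-of-fold scoring is disciplined, complete, and deterministic", {
  set.seed(51)
  X <- matrix(rnorm(300 * 5), 300, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(300, 1, plogis(X[, 1]))
  b <- train_gbdt_cv(X, y, k = 5, params = tiny_params, seed = 9)
  expect_equal(length(b$oof), 300)
  expect_true(all(b$oof > 0 & b$oof < 1))
  # each fold holds both classes (stratification)
  expect_true(all(sapply(1:5, function(f) length(unique(y[b$fold == f])) == 2)))
  # oof score for fold f comes from the model that excluded fold f
  for (f in 1:5) {
    i <- b$fold == f
    pred <- predict(b$models[[f]], xgboost::xgb.DMatrix(X[i, , drop = FALSE]))
    expect_equal(b$oof[i], pred, tolerance = 1e-12)
  }
  # and differs from the full-data model's scores
  full <- predict(b$full_model, xgboost::xgb.DMatrix(X))
  expect_false(isTRUE(all.equal(b$oof, full, tolerance = 1e-6)))
  b2 <- train_gbdt_cv(X, y, k = 5, params = tiny_params, seed = 9)
  expect_identical(b$oof, b2$oof)

  l <- train_logreg_cv(X, y, k = 5, seed = 9)
  l2 <- train_logreg_cv(X, y, k = 5, seed = 9)
  expect_identical(l$oof, l2$oof)
  expect_true(all(l$oof > 0 & l$oof < 1))
})

test_that("a strong planted architecture yields out-of-fold AUC > 0.85", {
  co <- strong_architecture(61, n = 5000)
  fx <- assemble_features(co)
  b <- train_gbdt_cv(fx$X, co$samples$label, seed = 61)
  expect_gt(auc(b$oof, co$samples$label), 0.85)
})

test_that("auc matches brute-force pair counting with tie handling", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  set.seed(71)
  s <- sample(1:5, 10, replace = TRUE)   # forces ties
  y <- rbinom(10, 1, 0.5); y[1] <- 1; y[2] <- 0
  brute <- mean(outer(s[y == 1], s[y == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc(s, y), brute, tolerance = 1e-12)
  # label-independent scores hover at 0.5
  set.seed(72)
  aucs <- replicate(200, auc(rnorm(60), rbinom(60, 1, 0.5)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("average_precision matches a hand-computed PR integral", {
  # thresholds 3, 2, 1: precision 1, 1/2, 2/3 at recall 1/2, 1/2, 1
  expect_equal(average_precision(c(3, 2, 1), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(average_precision(c(5, 4, 1), c(1, 1, 0)), 1)
})

test_that("delong_test handles identity and detects real differences", {
  set.seed(81)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(2 * x))
  same <- delong_test(x, x, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  better <- delong_test(x + rnorm(200, sd = 0.1), rnorm(200), y)
  expect_lt(better$p, 0.001)
})

test_that("mcnemar_test reproduces the exact and chi-square oracles", {
  # (10, 0): exact two-sided binomial p = 2 * 0.5^10
  e <- mcnemar_test(10, 0)
  expect_equal(e$method, "exact")
  expect_equal(e$p, 2 * 0.5^10, tolerance = 1e-12)
  # (15, 5): continuity-corrected chi-square = (10 - 1)^2 / 20 = 4.05
  c <- mcnemar_test(15, 5)
  expect_equal(c$method, "chisq")
  expect_equal(c$p, pchisq(4.05, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(c$p, 0.04417, tolerance = 1e-4)
  expect_equal(mcnemar_test(0, 0)$p, 1)
})

test_that("mcnemar_strata reports FN/FP discordance by stratum", {
  y <- rep(c(1, 0), each = 40)
  strata <- rep(c("A", "B"), 40)
  pred_a <- y; pred_b <- y
  out0 <- mcnemar_strata(pred_a, pred_b, y, strata)
  expect_true(all(out0$diff == 0))
  expect_true(all(out0$p == 1))
  # model fixes 6 of baseline's false negatives in stratum A
  pred_a2 <- y; pred_a2[which(y == 1 & strata == "A")[1:6]] <- 0
  out <- mcnemar_strata(pred_a2, pred_b, y, strata)
  fnA <- out[out$stratum == "A" & out$type == "FN", ]
  expect_equal(fnA$n_ab, 6)
  expect_equal(fnA$n_ba, 0)
  expect_gt(fnA$diff, 0)   # baseline minus model
})

test_that("youden_scale rows are internally consistent Table-style rows", {
  set.seed(91)
  y <- rbinom(2000, 1, 0.4)
  s <- rnorm(2000, mean = y)
  st <- youden_scale(s, y)
  expect_equal(st$case_centile, c(seq(5, 50, by = 5), 75, 95))
  expect_equal(st$youden,
               st$sensitivity / 100 + st$specificity / 100 - 1,
               tolerance = 1e-10)
  # monotone trade-off across rising thresholds
  expect_true(all(diff(st$sensitivity) <= 0))
  expect_true(all(diff(st$specificity) >= 0))
  expect_true(all(diff(st$threshold) >= 0))
})

test_that("youden_index accepts fractions and percentages", {
  expect_equal(youden_index(1, 1), 1)
  expect_equal(youden_index(0.9001, 0.8278), 0.7279, tolerance = 1e-9)
  expect_equal(youden_index(90.01, 82.78), 0.7279, tolerance = 1e-9)
})

test_that("additive_grs computes weighted dosage sums with class terms", {
  X <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(additive_grs(X, c(a = 0, b = 0)), c(0, 0, 0))
  expect_equal(additive_grs(X, c(a = 1)), X[, "a"], ignore_attr = TRUE)
  cls <- factor(c("DR3/DR4", "none", "none"))
  with_cls <- additive_grs(X, c(a = 1), class_weights = c("DR3/DR4" = 2),
                           mhc_class = cls)
  expect_equal(with_cls - additive_grs(X, c(a = 1)), c(2, 0, 0))
  expect_error(additive_grs(X, c(zz = 1)), "zz")
})
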