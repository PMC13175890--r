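tiny_params <- list(trees = 30L, depth = 3L, lr = 0.3, lambda = 1,
                    min_child_frac = 0)

# Small trained bundle on two informative + one null feature.
make_bundle <- function(seed = 101, n = 400) {
  set.seed(seed)
  X <- cbind(f1 = rbinom(n, 2, 0.4), f2 = rbinom(n, 2, 0.4),
             null = rep(0, n))
  storage.mode(X) <- "double"
  y <- rbinom(n, 1, plogis(-0.5 + 0.9 * X[, "f1"] + 0.3 * X[, "f2"]))
  list(X = X, y = y,
       bundle = train_gbdt_cv(X, y, k = 4, params = tiny_params, seed = seed))
}

test_that("compute_shap satisfies local accuracy for oof and full attributions", {
  mb <- make_bundle()
  for (use in c("oof", "full")) {
    sh <- compute_shap(mb$bundle, mb$X, use = use)
    expect_equal(sh$base + rowSums(sh$values), sh$margin, tolerance = 1e-5)
  }
  lr <- train_logreg_cv(mb$X[, 1:2], mb$y, k = 4, seed = 1)
  expect_error(compute_shap(lr, mb$X[, 1:2]), "tree-ensemble")
})

test_that("a single-split stump yields the closed-form leaf-difference attribution", {
  set.seed(5)
  x <- rbinom(500, 1, 0.5)
  y <- rbinom(500, 1, plogis(-1 + 2 * x))
  X <- cbind(x = as.double(x))
  m <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 1, eta = 1,
                  reg_lambda = 0, nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 1, verbose = 0)
  dm <- xgboost::xgb.DMatrix(X)
  contrib <- predict(m, dm, predcontrib = TRUE)
  margin <- predict(m, dm, outputmargin = TRUE)
  # phi = margin - cover-weighted expectation = margin - mean over training rows
  expect_equal(contrib[, "x"], margin - mean(margin), tolerance = 1e-6)
  expect_equal(contrib[, "(Intercept)"] + contrib[, "x"], margin,
               tolerance = 1e-6)
})

test_that("importance_ranking orders by mean |SHAP| with sensible extremes", {
  mb <- make_bundle()
  sh <- compute_shap(mb$bundle, mb$X, use = "full")
  imp <- importance_ranking(sh)
  expect_equal(imp$feature[1], "f1")           # planted dominant feature
  expect_equal(imp$feature[3], "null")         # constant column
  expect_equal(imp$importance[3], 0)
  # ranking invariant to row permutation
  perm <- sample(nrow(mb$X))
  sh2 <- sh; sh2$values <- sh$values[perm, ]
  expect_equal(importance_ranking(sh2), imp)
})

test_that("interaction tensors are symmetric and row-consistent with phi", {
  mb <- make_bundle()
  it <- compute_interactions(mb$bundle, mb$X, max_rows = 100, seed = 2)
  expect_equal(dim(it$tensor), c(100, 3, 3))
  expect_equal(it$tensor, aperm(it$tensor, c(1, 3, 2)), tolerance = 1e-4)
  # summing a feature's row of the tensor recovers its attribution
  for (j in 1:3)
    expect_equal(rowSums(it$tensor[, j, ]), it$phi[, j], tolerance = 1e-4)
})

test_that("purely additive signals leave off-diagonal interaction mass small", {
  set.seed(12)
  n <- 3000
  X <- cbind(a = rbinom(n, 2, 0.4), b = rbinom(n, 2, 0.4),
             c = rbinom(n, 2, 0.4))
  storage.mode(X) <- "double"
  y <- rbinom(n, 1, plogis(-1 + 0.8 * X[, "a"] + 0.8 * X[, "b"]))
  bundle <- train_gbdt_cv(X, y, k = 4, seed = 3)   # default regularization
  it <- compute_interactions(bundle, X, max_rows = 300, seed = 3)
  diag_scale <- mean(abs(vapply(1:3, function(j) it$tensor[, j, j], numeric(300))))
  offd <- mean(abs(c(it$tensor[, 1, 2], it$tensor[, 1, 3], it$tensor[, 2, 3])))
  # trees encode some incidental interaction even under additive truth, so
  # the off-diagonal mass is small relative to main effects, not zero
  expect_lt(offd, 0.25 * diag_scale)
})

test_that("interaction_significance standardizes against the pair background", {
  # hand-crafted tensor: pair (f1,f2) strong, (f1,f3) at the background mean
  n <- 50; p <- 4
  tensor <- array(0, dim = c(n, p, p),
                  dimnames = list(NULL, paste0("f", 1:p), paste0("f", 1:p)))
  fill <- function(i, j, v) {
    tensor[, i, j] <<- v / 2; tensor[, j, i] <<- v / 2
  }
  fill(1, 2, 5)      # dominant pair
  fill(1, 3, 1); fill(1, 4, 1); fill(2, 3, 1)
  fill(2, 4, 1); fill(3, 4, 1)
  it <- structure(list(tensor = tensor, phi = matrix(0, n, p),
                       rows = 1:n, features = paste0("f", 1:p)),
                  class = "interaction_tensor")
  groups <- setNames(c("MHC", "NON_MHC", "NON_MHC", "NON_MHC"),
                     paste0("f", 1:p))
  sig <- interaction_significance(it, groups = groups)
  expect_equal(nrow(sig), 6)
  expect_equal(c(sig$id_a[1], sig$id_b[1]), c("f1", "f2"))
  expect_equal(sig$category[1], "MHC-nonMHC")
  expect_equal(sig$category[sig$id_a == "f3" & sig$id_b == "f4"],
               "nonMHC-nonMHC")
  # statistic of the five background pairs sits below the mean; pairs at
  # exactly the background mean would get z = 0
  mu <- mean(sig$mean_abs)
  at_mean <- abs(sig$mean_abs - mu) < 1e-12
  expect_true(all(abs(sig$z[at_mean]) < 1e-12))
  expect_true(all(sig$q >= sig$p))
})

test_that("a planted MHC x non-MHC interaction tops the significance ranking", {
  rep1 <- interaction_replicate(seed = 7, epistatic = TRUE, n = 6000,
                                max_rows = 200)
  expect_true(rep1$top_hit)
  expect_equal(rep1$table$category[1], "MHC-nonMHC")
})

test_that("complexity_scores computes total displacement with balanced deciles", {
  sh <- structure(list(values = rbind(c(0, 0, 0), c(0.5, -0.25, 0.25))),
                  class = "shap_matrix")
  cx <- complexity_scores(sh)
  expect_equal(cx$complexity, c(0, 1))
  sh2 <- structure(list(values = matrix(rnorm(105 * 3), 105)),
                   class = "shap_matrix")
  d <- complexity_scores(sh2)$decile
  expect_true(all(abs(table(d) - 10.5) <= 0.5))
})

test_that("performance_by_complexity reports per-decile AUCs and deltas", {
  set.seed(14)
  y <- rbinom(600, 1, 0.4)
  s <- rnorm(600, y)
  dec <- t1grslab:::ntile_int(rnorm(600), 10L)
  out <- performance_by_complexity(list(m1 = s, m2 = s), y, dec)
  expect_equal(out$delta, rep(0, nrow(out)))
  expect_true(all(out$m1 >= 0 & out$m1 <= 1))
  expect_equal(out$decile, 1:10)
})

test_that("component_attribution sums groups consistently by stratum", {
  set.seed(16)
  vals <- matrix(rnorm(200 * 4), 200,
                 dimnames = list(NULL, c("m1", "m2", "g1", "g2")))
  sh <- structure(list(values = vals,
                       groups = setNames(c("MHC", "MHC", "NON_MHC", "NON_MHC"),
                                         colnames(vals))),
                  class = "shap_matrix")
  strata <- rep(c("A", "B"), 100)
  out <- component_attribution(sh, strata = strata)
  expect_equal(nrow(out), 4)
  totals <- aggregate(rowSums(vals), list(strata), mean)$x
  group_totals <- tapply(out$mean_sum, out$stratum, sum)
  expect_equal(as.numeric(group_totals), totals, tolerance = 1e-12)
})

test_that("2-D partial dependence separates additive from interacting pairs", {
  set.seed(18)
  n <- 2000
  X <- cbind(a = rbinom(n, 2, 0.5), b = rbinom(n, 2, 0.5))
  storage.mode(X) <- "double"
  y_add <- rbinom(n, 1, plogis(-1 + 0.9 * X[, "a"] + 0.9 * X[, "b"]))
  y_int <- rbinom(n, 1, plogis(-1.5 + 1.2 * X[, "a"] * X[, "b"]))
  b_add <- train_gbdt_cv(X, y_add, k = 4, seed = 4)
  b_int <- train_gbdt_cv(X, y_int, k = 4, seed = 4)
  pd_add <- partial_dependence_2d(b_add, X, c("a", "b"))
  pd_int <- partial_dependence_2d(b_int, X, c("a", "b"))
  expect_equal(dim(pd_add$surface), c(3, 3))
  expect_gt(pd_int$contrast, 0.5)
  expect_lt(abs(pd_add$contrast), pd_int$contrast / 3)
})
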