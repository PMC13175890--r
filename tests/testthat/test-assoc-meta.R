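test_that("firth_logistic stays finite under complete separation", {
  y <- c(rep(1, 20), rep(0, 30))
  x <- c(rep(1, 20), rep(0, 30))   # all cases carry, no control does
  fit <- firth_logistic(y, x)
  expect_true(is.finite(fit$beta))
  expect_true(is.finite(fit$se) && fit$se > 0)
  expect_true(fit$converged)
  expect_gt(fit$beta, 0)
})

test_that("firth_logistic matches a grid maximization of the penalized likelihood", {
  # collapsed 2x2 toy: counts (cases/controls) by carrier status
  y <- c(rep(1, 18), rep(0, 7), rep(1, 9), rep(0, 26))
  x <- c(rep(1, 25), rep(0, 35))
  fit <- firth_logistic(y, x)
  pen_ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    pr <- plogis(eta)
    X <- cbind(1, x)
    info <- crossprod(X, X * pr * (1 - pr))
    sum(y * eta - log1p(exp(eta))) + 0.5 * log(det(info))
  }
  # profile the intercept over a fine slope grid around the fit
  grid <- seq(fit$beta - 0.3, fit$beta + 0.3, by = 1e-3)
  prof <- vapply(grid, function(b1)
    stats::optimize(function(b0) pen_ll(b0, b1), c(-5, 5),
                    maximum = TRUE)$objective, 0)
  expect_lt(abs(grid[which.max(prof)] - fit$beta), 1e-3 + 1e-9)
  # the fitted point is at least as good as the best grid point
  b0_hat <- fit$coef[["(Intercept)"]]
  expect_gte(pen_ll(b0_hat, fit$beta) + 1e-8, max(prof))
})

test_that("firth p-values are approximately uniform under permutation", {
  set.seed(42)
  x <- rbinom(500, 2, 0.3)
  y <- rbinom(500, 1, 0.3)
  ps <- vapply(1:200, function(i) {
    firth_logistic(sample(y), x)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(abs(mean(ps < 0.05) - 0.05) < 0.05)
})

test_that("firth_logistic rejects degenerate designs with named columns", {
  y <- rbinom(100, 1, 0.4)
  x <- rbinom(100, 2, 0.3)
  expect_error(firth_logistic(y, rep(1, 100), variant_id = "var007"),
               "var007")
  expect_error(firth_logistic(rep(1, 100), x), "case")
  covars <- cbind(dup1 = x, dup2 = x)   # collinear with the dosage
  expect_error(firth_logistic(y, x, covars), "dup")
})

test_that("penalized LRT agrees with Wald on strong signals", {
  set.seed(8)
  x <- rbinom(2000, 2, 0.3)
  y <- rbinom(2000, 1, plogis(-1 + 0.6 * x))
  w <- firth_logistic(y, x, p_method = "wald")
  l <- firth_logistic(y, x, p_method = "plrt")
  expect_lt(w$p, 1e-10)
  expect_lt(l$p, 1e-10)
  expect_equal(w$beta, l$beta)
})

test_that("ivw_meta matches hand calculations", {
  r <- function(b, s) list(variant_id = "v", beta = b, se = s, n = 100)
  m <- ivw_meta(list(r(0.5, 0.1), r(0.5, 0.1)))
  expect_equal(m$beta, 0.5)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-9)
  one <- ivw_meta(list(r(0.3, 0.15)))
  expect_equal(one$beta, 0.3)
  expect_equal(one$se, 0.15)
  m2 <- ivw_meta(list(r(0.2, 0.1), r(0.6, 0.2)))
  expect_equal(m2$beta, 0.28, tolerance = 1e-9)        # (20 + 15) / 125
  expect_equal(m2$se, 1 / sqrt(125), tolerance = 1e-9) # 0.089443
  expect_equal(m2$n_total, 200)
  bad <- list(r(0.2, 0.1), list(variant_id = "w", beta = 0.1, se = 0.1))
  expect_error(ivw_meta(bad), "mismatched")
})

test_that("assoc_scan applies the MAF filter and recovers planted effects", {
  p <- variant_panel(6, n_blocks = 2)
  p$maf[6] <- 0.004
  eff <- effect_spec(additive = c(var002 = 0.5), intercept = qlogis(0.3))
  co <- simulate_cohort(4000, p, eff, ld_rho = 0, seed = 17)
  cl <- t1grslab:::pipeline_cohort_list(co)
  res <- assoc_scan(cl, maf_min = 0.01)
  expect_false("var006" %in% res$variant_id)
  expect_equal(nrow(res), 5)
  expect_lt(res$p[res$variant_id == "var002"], 1e-8)
  b <- res$beta[res$variant_id == "var002"]
  s <- res$se[res$variant_id == "var002"]
  expect_lt(abs(b - 0.5), 3 * s)
})

test_that("clumping and locus definition follow the two-round rules", {
  ids <- sprintf("v%02d", 1:5)
  meta <- data.frame(variant_id = ids, chrom = "6",
                     pos = c(1e6, 1.01e6, 3e6, 5e6, 9e6),
                     p = c(1e-10, 1e-9, 0.2, 0.3, 0.6))
  ld <- diag(5); dimnames(ld) <- list(ids, ids)
  ld["v01", "v02"] <- ld["v02", "v01"] <- 0.5
  # two significant variants in LD 10 kb apart -> one clump, index = min p
  loci <- clump_and_define_loci(meta, ld)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$index, "v01")
  expect_true(grepl("v02", loci$members))
  expect_equal(loci$start, as.integer(1e6 - 5e5))
  expect_equal(loci$end, as.integer(1e6 + 5e5))
  # no variant below 5e-8 -> empty locus list
  meta0 <- meta; meta0$p <- pmax(meta0$p, 1e-6)
  expect_equal(nrow(clump_and_define_loci(meta0, ld)), 0)
  # with no LD at all, every significant variant indexes its own locus
  ld2 <- diag(5); dimnames(ld2) <- list(ids, ids)
  meta2 <- meta; meta2$p[4] <- 1e-9
  loci2 <- clump_and_define_loci(meta2, ld2)
  expect_equal(sort(loci2$index), c("v01", "v02", "v04"))
})

test_that("stepwise_conditional recovers planted independent signals", {
  p <- variant_panel(8, n_blocks = 8)   # independent blocks
  eff <- effect_spec(additive = c(var002 = 0.47, var006 = 0.47),
                     intercept = qlogis(0.35))
  co <- simulate_cohort(6000, p, eff, ld_rho = 0, seed = 23)
  cl <- t1grslab:::pipeline_cohort_list(co)
  sig <- stepwise_conditional(cl, p$id)
  expect_equal(sort(sig$variant_id), c("var002", "var006"))
  expect_equal(sig$rank, seq_len(nrow(sig)))
  expect_equal(sig$conditioning[1], "")
  expect_equal(sig$conditioning[2], sig$variant_id[1])
})

test_that("stepwise_conditional reports one signal for a shadowed variant", {
  p <- variant_panel(4, n_blocks = 2)   # var001+var002 share a block
  eff <- effect_spec(additive = c(var001 = 0.5), intercept = qlogis(0.35))
  co <- simulate_cohort(6000, p, eff, ld_rho = 0.9, seed = 29)
  cl <- t1grslab:::pipeline_cohort_list(co)
  sig <- stepwise_conditional(cl, p$id)
  expect_equal(nrow(sig), 1)
  expect_true(sig$variant_id %in% c("var001", "var002"))
  # null region -> empty result
  null_sig <- stepwise_conditional(cl, c("var003", "var004"))
  expect_equal(nrow(null_sig), 0)
})

test_that("build_precondition_covariates yields 70 + 20 = 90 columns", {
  p <- variant_panel(90)
  G <- simulate_genotypes(p, 80, seed = 3)
  alleles <- p$id[1:70]
  pairs <- data.frame(id_a = p$id[71:90], id_b = p$id[1:20])
  M <- build_precondition_covariates(G, alleles, pairs)
  expect_equal(ncol(M), 90)
  B <- M[, 71:90]
  expect_true(all(B %in% c(0, 1)))
  # interaction entry 0 whenever one member has dosage 0
  r <- which(G[, "var071"] == 0)[1]
  expect_equal(M[r, "pair_var071_var001"], 0, ignore_attr = TRUE)
  expect_error(build_precondition_covariates(G, "nope"), "nope")
})
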