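test_that("embed_shap caps dimensions and is deterministic", {
  arc <- simulate_shap_archetypes(150, n_features = 12, k = 3, seed = 1)
  emb <- embed_shap(arc$shap, n_pcs = 500, k = 500)
  expect_lte(ncol(emb$pcs), 12)
  expect_equal(emb$k, 149)
  emb2 <- embed_shap(arc$shap, n_pcs = 500, k = 500)
  expect_identical(emb$pcs, emb2$pcs)
  expect_identical(emb$knn, emb2$knn)
})

test_that("far-separated archetypes produce almost no cross-archetype edges", {
  arc <- simulate_shap_archetypes(400, n_features = 20, k = 2,
                                  separation = 12, seed = 2)
  emb <- embed_shap(arc$shap, k = 20)
  el <- igraph::as_edgelist(emb$graph)
  cross <- mean(arc$subtype[el[, 1]] != arc$subtype[el[, 2]])
  expect_lt(cross, 0.01)
})

test_that("cluster_shap recovers planted archetypes and collapses at tiny resolution", {
  arc <- simulate_shap_archetypes(800, n_features = 40, k = 4, seed = 3)
  emb <- embed_shap(arc$shap, k = 60)
  ca <- cluster_shap(emb, resolution = 0.05, seed = 4)
  expect_equal(ca$k, 4)
  expect_gte(ari(ca$labels, arc$subtype), 0.9)
  # labels renumbered by descending size
  sizes <- as.integer(table(ca$labels))
  expect_true(all(diff(sizes) <= 0))
  # collapse at tiny resolution needs a connected graph, so use one blob:
  # Leiden cannot merge the disconnected components of well-separated
  # archetypes no matter how small the resolution
  blob <- simulate_shap_archetypes(300, n_features = 40, k = 1, seed = 31)
  emb0 <- embed_shap(blob$shap, k = 30)
  ca0 <- cluster_shap(emb0, resolution = 1e-9, seed = 4)
  expect_equal(ca0$k, 1)
})

test_that("choose_k selects the planted cluster number by silhouette", {
  arc <- simulate_shap_archetypes(600, n_features = 40, k = 4, seed = 5)
  emb <- embed_shap(arc$shap, k = 60)
  ck <- choose_k(emb, seed = 6)
  expect_equal(ck$chosen_k, 4)
  expect_true(all(is.na(ck$diagnostics$silhouette[ck$diagnostics$k == 1])))
})

test_that("layout_2d yields separated 2-D point clouds", {
  arc <- simulate_shap_archetypes(300, n_features = 20, k = 3,
                                  separation = 6, seed = 7)
  emb <- embed_shap(arc$shap, k = 30)
  for (method in c("pca", "fr")) {
    xy <- layout_2d(emb, method = method, seed = 8)
    expect_equal(dim(xy), c(300, 2))
    cents <- sapply(1:3, function(a) colMeans(xy[arc$subtype == a, ]))
    between <- mean(dist(t(cents)))
    within <- mean(sqrt(rowSums((xy - t(cents)[arc$subtype, ])^2)))
    expect_gt(between / within, 2)
  }
  expect_identical(layout_2d(emb, "fr", seed = 8), layout_2d(emb, "fr", seed = 8))
})

test_that("project_validation is self-consistent and proportion-preserving", {
  arc <- simulate_shap_archetypes(600, n_features = 40, k = 4, seed = 9)
  emb <- embed_shap(arc$shap, k = 60)
  ca <- cluster_shap(emb, seed = 10)
  self <- project_validation(arc$shap, emb, ca$labels)
  expect_gte(mean(self$labels == ca$labels), 0.99)
  val <- simulate_shap_archetypes(400, n_features = 40, k = 4, seed = 11)
  proj <- project_validation(val$shap, emb, ca$labels)
  disc_prop <- as.numeric(table(ca$labels)) / length(ca$labels)
  expect_true(all(abs(proj$proportions - disc_prop) < 0.05))
  empty <- project_validation(arc$shap[0, , drop = FALSE], emb, ca$labels)
  expect_equal(length(empty$labels), 0)
  expect_equal(length(empty$centroid_distance), 0)
})

test_that("cluster_feature_stats flags planted dominant features", {
  set.seed(12)
  X <- matrix(rnorm(300 * 6, mean = 1, sd = 0.2), 300,
              dimnames = list(NULL, paste0("f", 1:6)))
  labels <- rep(1:2, each = 150)
  X[labels == 1, "f1"] <- X[labels == 1, "f1"] + 3
  st <- cluster_feature_stats(X, labels)
  top1 <- st[st$cluster == 1, ][which.max(st$log2fc[st$cluster == 1]), ]
  expect_equal(top1$feature, "f1")
  expect_lt(top1$p, 0.01)
  # identical feature -> log2fc 0; two-cluster antisymmetry
  f2 <- st[st$feature == "f2", ]
  expect_equal(f2$log2fc[1], -f2$log2fc[2], tolerance = 1e-10)
  expect_lt(abs(f2$log2fc[1]), 0.2)
})

test_that("top_cluster_loci assigns by the share > threshold rule", {
  X <- matrix(0.25, 8, 2, dimnames = list(NULL, c("even", "dominant")))
  labels <- rep(1:4, 2)
  X[labels == 2, "dominant"] <- 4
  out <- top_cluster_loci(X, labels, threshold = 0.75)
  expect_equal(rowSums(out$shares), c(even = 1, dominant = 1),
               tolerance = 1e-12)
  expect_equal(out$assignment$feature, "dominant")
  expect_equal(out$assignment$cluster, 2)
  expect_false("even" %in% out$assignment$feature)
  # shares sum to one, so assignments are unique per feature
  expect_false(any(duplicated(out$assignment$feature)))
})

test_that("celltype_enrichment detects planted enrichment with an add-one floor", {
  planted <- data.frame(cluster = 1,
                        variant_id = sprintf("v%02d", 1:20),
                        pip = c(rep(0.9, 5), rep(0.01, 15)),
                        celltype = c(rep("beta", 5), sample(c("T", "B"), 15,
                                                            replace = TRUE)))
  set.seed(13)
  enr <- celltype_enrichment(planted, n_perm = 999, seed = 14)
  expect_lt(enr$p[enr$celltype == "beta"], 0.01)
  expect_true(all(enr$p >= 1 / 1000))
  # null labels give unremarkable p-values on average
  set.seed(15)
  ps <- replicate(20, {
    d <- data.frame(cluster = 1, variant_id = sprintf("v%02d", 1:20),
                    pip = runif(20),
                    celltype = sample(c("a", "b"), 20, replace = TRUE))
    celltype_enrichment(d, n_perm = 199, seed = sample.int(1e6, 1))$p[1]
  })
  expect_gt(mean(ps), 0.2)
})

test_that("onset_logrank detects a +5-year shift and rejects single clusters", {
  spec <- clinical_spec(onset = data.frame(subtype = c("s1", "s2"),
                                           location = c(15, 10), scale = 3))
  sub <- rep(c("s1", "s2"), each = 1000)
  clin <- simulate_clinical(sub, spec, seed = 16)
  lr <- onset_logrank(clin$onset_age, as.integer(factor(sub)))
  expect_lt(lr$overall$p, 0.01)
  expect_gt(lr$per_cluster$median_onset[1], lr$per_cluster$median_onset[2])
  expect_error(onset_logrank(clin$onset_age, rep(1, 2000)), "two clusters")
})

test_that("complication_assoc recovers a planted odds ratio and corrects zero cells", {
  set.seed(17)
  labels <- rep(1:2, c(5000, 15000))
  p0 <- 0.12
  p1 <- plogis(qlogis(p0) + log(1.46))
  event <- rbinom(20000, 1, ifelse(labels == 1, p1, p0))
  out <- complication_assoc(event, labels, target = 1)
  expect_true(out$ci[1] < 1.46 && 1.46 < out$ci[2])
  expect_lt(abs(out$or - 1.46), 0.25)
  # null labels: CI covers 1
  event0 <- rbinom(20000, 1, p0)
  out0 <- complication_assoc(event0, labels, target = 1)
  expect_true(out0$ci[1] < 1 && 1 < out0$ci[2])
  # zero cell triggers the continuity correction with a warning
  expect_warning(
    z <- complication_assoc(c(1, 1, 0, 0), c(1, 1, 2, 2), target = 1),
    "continuity")
  expect_true(is.finite(z$or))
})

test_that("t2d_enrichment finds planted locus-label association", {
  shares <- matrix(c(0.9, 0.85, 0.8, 0.1, 0.15, 0.1,
                     0.1, 0.15, 0.2, 0.9, 0.85, 0.9), 6, 2,
                   dimnames = list(sprintf("locus%d", 1:6), c("c1", "c2")))
  t2d <- setNames(c(1, 1, 1, 0, 0, 0), rownames(shares))
  out <- t2d_enrichment(shares, t2d)
  expect_gt(out$beta[out$cluster == "c1"], 0)
  expect_lt(out$beta[out$cluster == "c2"], 0)
  expect_error(t2d_enrichment(shares, setNames(rep(1, 6), rownames(shares))),
               "degenerate")
})
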