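# SHAP-space subtype discovery: PCA embedding, kNN graph, Leiden
# clustering, validation projection and per-cluster characterization.

# Chunked exact k-nearest-neighbour search in Euclidean space; returns an
# n x k index matrix. Avoids materializing the full n x n distance matrix.
knn_indices <- function(X, k, ref = X, self = TRUE, chunk = 512L) {
  n <- nrow(X); m <- nrow(ref)
  k <- min(k, m - if (self) 1L else 0L)
  rn_ref <- rowSums(ref^2)
  out <- matrix(0L, n, k)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D <- outer(rowSums(X[s:e, , drop = FALSE]^2), rn_ref, `+`) -
      2 * tcrossprod(X[s:e, , drop = FALSE], ref)
    if (self) D[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    out[s:e, ] <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  }
  out
}

#' PCA embedding and kNN graph of a SHAP matrix
#'
#' Centers the attribution matrix, retains up to `n_pcs` principal
#' components (capped at the data rank), and links each individual to its
#' `k` nearest Euclidean neighbours in PC space (k capped at n - 1). The
#' graph is undirected with no self-edges.
#'
#' @param shap Attribution matrix (individuals x features) or a
#'   `shap_matrix`.
#' @param n_pcs Maximum number of principal components (default 175).
#' @param k Neighbours per individual (default 120).
#' @return An `shap_embedding`: list with `pcs`, `center`, `rotation`,
#'   `var_explained`, `graph` (igraph), `knn`, `k`.
#' @export
embed_shap <- function(shap, n_pcs = 175L, k = 120L) {
  X <- if (inherits(shap, "shap_matrix")) shap$values else as.matrix(shap)
  n <- nrow(X)
  n_pcs <- min(n_pcs, n - 1L, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  k <- min(k, n - 1L)
  nn <- knn_indices(pc$x, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  structure(list(pcs = pc$x, center = pc$center, rotation = pc$rotation,
                 var_explained = pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2),
                 graph = g, knn = nn, k = k),
            class = "shap_embedding")
}

#' Leiden clustering of the kNN graph
#'
#' Community detection with the modularity objective at the given
#' resolution; labels are renumbered by descending cluster size for
#' cross-run comparability.
#'
#' @param embedding An `shap_embedding`.
#' @param resolution Leiden resolution parameter (default 0.05).
#' @param seed Integer seed (the refinement step is stochastic).
#' @param n_iterations Leiden iterations.
#' @return A `cluster_assignment`: list with `labels` (integer, 1-based,
#'   descending size), `k`, `resolution`.
#' @export
cluster_shap <- function(embedding, resolution = 0.05, seed = 1L,
                         n_iterations = 5L) {
  set.seed(seed)
  cl <- igraph::cluster_leiden(embedding$graph,
                               objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  lab <- igraph::membership(cl)
  sizes <- sort(table(lab), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(lab)])
  structure(list(labels = labels, k = length(sizes), resolution = resolution),
            class = "cluster_assignment")
}

#' Choose the cluster number from silhouette and inertia diagnostics
#'
#' Runs the Leiden clustering across candidate resolutions and scores each
#' distinct partition by mean silhouette width (in PC space) and total
#' within-cluster sum of squares (inertia). Single-cluster partitions have
#' no silhouette and are excluded; the chosen k maximizes the silhouette.
#'
#' @param embedding An `shap_embedding`.
#' @param resolutions Candidate resolution values.
#' @param seed Integer seed.
#' @return List: `chosen_k`, `chosen_resolution`, `diagnostics` (data frame
#'   with `resolution`, `k`, `silhouette`, `inertia`), `assignments`.
#' @export
choose_k <- function(embedding, resolutions = c(0.01, 0.025, 0.05, 0.1, 0.25,
                                                0.5, 1),
                     seed = 1L) {
  pcs <- embedding$pcs
  d <- stats::dist(pcs)
  rows <- list(); assigns <- list()
  for (res in resolutions) {
    ca <- cluster_shap(embedding, resolution = res, seed = seed)
    sil <- if (ca$k >= 2)
      mean(cluster::silhouette(ca$labels, d)[, "sil_width"]) else NA_real_
    inertia <- sum(vapply(seq_len(ca$k), function(c0) {
      Xi <- pcs[ca$labels == c0, , drop = FALSE]
      sum(scale(Xi, scale = FALSE)^2)
    }, 0))
    rows[[length(rows) + 1L]] <- data.frame(resolution = res, k = ca$k,
                                            silhouette = sil,
                                            inertia = inertia)
    assigns[[as.character(res)]] <- ca
  }
  diag <- do.call(rbind, rows)
  ok <- which(!is.na(diag$silhouette))
  best <- ok[which.max(diag$silhouette[ok])]
  list(chosen_k = diag$k[best], chosen_resolution = diag$resolution[best],
       diagnostics = diag, assignments = assigns)
}

#' Two-dimensional layout of the embedding
#'
#' Presentation-only coordinates: either the first two principal
#' components (`"pca"`, deterministic) or a seeded Fruchterman-Reingold
#' layout of the kNN graph (`"fr"`).
#'
#' @param embedding An `shap_embedding`.
#' @param method `"pca"` or `"fr"`.
#' @param seed Integer seed (used by `"fr"`).
#' @return Numeric n x 2 coordinate matrix.
#' @export
layout_2d <- function(embedding, method = c("pca", "fr"), seed = 1L) {
  method <- match.arg(method)
  if (method == "pca") {
    xy <- embedding$pcs[, 1:2, drop = FALSE]
  } else {
    set.seed(seed)
    xy <- igraph::layout_with_fr(embedding$graph)
  }
  colnames(xy) <- c("dim1", "dim2")
  xy
}

#' Project a validation cohort onto discovery clusters
#'
#' Validation attribution rows are centered with the discovery means,
#' rotated by the discovery loadings, and assigned by majority vote of the
#' k nearest discovery neighbours in PC space; per-cluster centroid
#' distances are reported.
#'
#' @param val_shap Validation attribution matrix (same features).
#' @param embedding Discovery `shap_embedding`.
#' @param labels Discovery cluster labels.
#' @param k Neighbours for the vote (defaults to the embedding's k).
#' @return List: `labels` (validation assignments), `centroid_distance`
#'   (per validation row, distance to its assigned cluster centroid),
#'   `proportions` (validation cluster shares).
#' @export
project_validation <- function(val_shap, embedding, labels, k = NULL) {
  X <- if (inherits(val_shap, "shap_matrix")) val_shap$values else
    as.matrix(val_shap)
  if (nrow(X) == 0)
    return(list(labels = integer(), centroid_distance = numeric(),
                proportions = numeric()))
  k <- k %||% embedding$k
  pcs_val <- sweep(X, 2, embedding$center) %*% embedding$rotation
  nn <- knn_indices(pcs_val, k, ref = embedding$pcs, self = FALSE)
  vote <- apply(nn, 1, function(i) {
    tab <- sort(table(labels[i]), decreasing = TRUE)
    as.integer(names(tab)[1])
  })
  cents <- t(sapply(sort(unique(labels)), function(c0)
    colMeans(embedding$pcs[labels == c0, , drop = FALSE])))
  cd <- sqrt(rowSums((pcs_val - cents[vote, , drop = FALSE])^2))
  list(labels = vote, centroid_distance = cd,
       proportions = as.numeric(table(factor(vote, sort(unique(labels)))) /
                                  length(vote)))
}

#' Per-cluster feature statistics
#'
#' For each cluster and feature: log2 fold-change of the mean absolute
#' attribution inside the cluster versus all other clusters, with a
#' two-sided t-test (raw and Benjamini-Hochberg adjusted p-values).
#'
#' @param shap Attribution matrix or `shap_matrix`.
#' @param labels Cluster labels.
#' @param eps Numerical floor for the fold-change ratio.
#' @return Data frame: `cluster`, `feature`, `log2fc`, `p`, `q`.
#' @export
cluster_feature_stats <- function(shap, labels, eps = 1e-12) {
  X <- abs(if (inherits(shap, "shap_matrix")) shap$values else as.matrix(shap))
  rows <- list()
  for (c0 in sort(unique(labels))) {
    i <- labels == c0
    m_in <- colMeans(X[i, , drop = FALSE])
    m_out <- colMeans(X[!i, , drop = FALSE])
    pv <- vapply(seq_len(ncol(X)), function(j) {
      xin <- X[i, j]; xout <- X[!i, j]
      if (stats::sd(xin) == 0 && stats::sd(xout) == 0) return(1)
      stats::t.test(xin, xout)$p.value
    }, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = c0, feature = colnames(X),
      log2fc = log2(pmax(m_in, eps) / pmax(m_out, eps)),
      p = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Top loci per cluster by normalized SHAP share
#'
#' Each feature's mean absolute attribution per cluster is normalized to
#' sum to one across clusters; a feature is assigned to a cluster iff its
#' share there exceeds the threshold (shares sum to one, so at most one
#' cluster can qualify).
#'
#' @param shap Attribution matrix or `shap_matrix`.
#' @param labels Cluster labels.
#' @param threshold Share threshold (default 0.75).
#' @return List: `shares` (feature x cluster matrix, rows sum to 1),
#'   `assignment` (data frame `feature`, `cluster`, `share` for assigned
#'   features).
#' @export
top_cluster_loci <- function(shap, labels, threshold = 0.75) {
  X <- abs(if (inherits(shap, "shap_matrix")) shap$values else as.matrix(shap))
  cl <- sort(unique(labels))
  m <- sapply(cl, function(c0) colMeans(X[labels == c0, , drop = FALSE]))
  colnames(m) <- as.character(cl)
  shares <- m / pmax(rowSums(m), 1e-300)
  hit <- which(shares > threshold, arr.ind = TRUE)
  assignment <- data.frame(feature = rownames(shares)[hit[, 1]],
                           cluster = cl[hit[, 2]],
                           share = shares[hit],
                           stringsAsFactors = FALSE)
  list(shares = shares, assignment = assignment)
}

#' Permutation enrichment of cluster loci in cell-type elements
#'
#' The observed statistic per cluster and cell type is the summed PIP of
#' the cluster's credible-set variants annotated to that cell type; the
#' null shuffles the cell-type labels across the cluster's variants
#' `n_perm` times. P-values use the add-one estimator and can never fall
#' below `1 / (n_perm + 1)`.
#'
#' @param credible Data frame with columns `cluster`, `variant_id`, `pip`,
#'   `celltype`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Data frame: `cluster`, `celltype`, `observed`, `p`.
#' @export
celltype_enrichment <- function(credible, n_perm = 10000L, seed = 1L) {
  stopifnot(all(c("cluster", "variant_id", "pip", "celltype") %in%
                  names(credible)))
  set.seed(seed)
  rows <- list()
  for (c0 in sort(unique(credible$cluster))) {
    d <- credible[credible$cluster == c0, ]
    cts <- sort(unique(d$celltype))
    obs <- vapply(cts, function(ct) sum(d$pip[d$celltype == ct]), 0)
    null_mat <- matrix(0, n_perm, length(cts), dimnames = list(NULL, cts))
    for (b in seq_len(n_perm)) {
      lab <- sample(d$celltype)
      s <- tapply(d$pip, factor(lab, cts), sum, default = 0)
      null_mat[b, ] <- s
    }
    for (ct in cts) {
      pval <- (1 + sum(null_mat[, ct] >= obs[[ct]] - 1e-12)) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- data.frame(cluster = c0, celltype = ct,
                                              observed = obs[[ct]], p = pval,
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Log-rank comparison of onset across clusters
#'
#' Overall log-rank test plus per-cluster one-versus-rest tests on the
#' (fully observed) ages of onset, with per-cluster median onset.
#'
#' @param onset Onset ages (cases).
#' @param labels Cluster labels (same length).
#' @return List: `overall` (`chisq`, `df`, `p`), `per_cluster` data frame
#'   (`cluster`, `chisq`, `p`, `median_onset`).
#' @export
onset_logrank <- function(onset, labels) {
  keep <- !is.na(onset) & !is.na(labels)
  onset <- onset[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop_named("log-rank needs at least two clusters")
  srv <- survival::Surv(onset, rep(1L, length(onset)))
  sd_all <- survival::survdiff(srv ~ factor(labels))
  overall <- list(chisq = sd_all$chisq, df = length(sd_all$n) - 1,
                  p = stats::pchisq(sd_all$chisq, length(sd_all$n) - 1,
                                    lower.tail = FALSE))
  per <- lapply(sort(unique(labels)), function(c0) {
    g <- factor(labels == c0)
    sd1 <- survival::survdiff(srv ~ g)
    data.frame(cluster = c0, chisq = sd1$chisq,
               p = stats::pchisq(sd1$chisq, 1, lower.tail = FALSE),
               median_onset = stats::median(onset[labels == c0]))
  })
  list(overall = overall, per_cluster = do.call(rbind, per))
}

#' Cluster-versus-rest complication odds ratio
#'
#' 2x2 odds ratio with a Woolf (log-scale) 95% confidence interval and a
#' two-sided Wald p-value; a Haldane continuity correction of 0.5 is
#' applied with a warning when any cell is zero. An optional Cox
#' proportional-hazards p-value is computed when onset times are supplied.
#'
#' @param event 0/1 complication indicator.
#' @param labels Cluster labels.
#' @param target Cluster compared against the rest.
#' @param onset Optional onset/follow-up times for the Cox model.
#' @return List: `or`, `ci` (length 2), `p`, `table`, `cox_p` (or `NA`).
#' @export
complication_assoc <- function(event, labels, target, onset = NULL) {
  keep <- !is.na(event) & !is.na(labels)
  event <- event[keep]; labels <- labels[keep]
  g <- labels == target
  a <- sum(event == 1 & g); b <- sum(event == 0 & g)
  c0 <- sum(event == 1 & !g); d0 <- sum(event == 0 & !g)
  tab <- matrix(c(a, b, c0, d0), 2, byrow = TRUE,
                dimnames = list(c("target", "rest"), c("event", "no_event")))
  if (any(tab == 0)) {
    warning("zero cell in 2x2 table; applying continuity correction of 0.5",
            call. = FALSE)
    a <- a + 0.5; b <- b + 0.5; c0 <- c0 + 0.5; d0 <- d0 + 0.5
  }
  or <- (a * d0) / (b * c0)
  se <- sqrt(1 / a + 1 / b + 1 / c0 + 1 / d0)
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  cox_p <- NA_real_
  if (!is.null(onset)) {
    onset <- onset[keep]
    fit <- survival::coxph(survival::Surv(onset, event) ~ g)
    cox_p <- summary(fit)$coefficients[1, "Pr(>|z|)"]
  }
  list(or = or, ci = ci, p = p, table = tab, cox_p = cox_p)
}

#' Enrichment of T2D-associated loci in cluster importance profiles
#'
#' Per cluster, logistic regression of the binary T2D-locus label on the
#' cluster's mean-normalized SHAP share per locus.
#'
#' @param shares Locus x cluster matrix of normalized importance shares
#'   (e.g. `top_cluster_loci()$shares`).
#' @param t2d_label Named 0/1 vector over loci.
#' @return Data frame: `cluster`, `beta`, `or`, `p`.
#' @export
t2d_enrichment <- function(shares, t2d_label) {
  stopifnot(all(rownames(shares) %in% names(t2d_label)))
  yl <- as.numeric(t2d_label[rownames(shares)])
  if (length(unique(yl)) < 2)
    stop_named("degenerate outcome: all loci share the same T2D label")
  rows <- lapply(colnames(shares), function(cl) {
    fit <- suppressWarnings(stats::glm(yl ~ shares[, cl], family = stats::binomial()))
    sm <- summary(fit)$coefficients
    data.frame(cluster = cl, beta = sm[2, 1], or = exp(sm[2, 1]),
               p = sm[2, 4], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
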