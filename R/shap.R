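#' Per-individual SHAP attributions from the tree ensemble
#'
#' Exact tree-path (TreeSHAP) attributions on the margin (log-odds) scale,
#' where the additive decomposition is exact: base value plus the row sum
#' of attributions equals the model margin for that individual (local
#' accuracy). With `use = "oof"` each individual is attributed by the fold
#' model that never saw them.
#'
#' @param bundle A `model_bundle` from [train_gbdt_cv()].
#' @param X Feature matrix the bundle was trained on (same columns).
#' @param use `"oof"` (per-fold, out-of-fold) or `"full"` (the
#'   representative full-data model).
#' @param groups Optional feature group labels to carry along.
#' @return A `shap_matrix`: list with `values` (n x p), `base` (per-row
#'   expected margin), `margin` (model margin per row), `groups`.
#' @export
compute_shap <- function(bundle, X, use = c("oof", "full"), groups = NULL) {
  use <- match.arg(use)
  if (!inherits(bundle, "model_bundle") || bundle$model_type != "gbdt")
    stop_named("SHAP attribution requires a tree-ensemble model bundle")
  stopifnot(identical(colnames(X), bundle$features))
  n <- nrow(X); p <- ncol(X)
  values <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  base <- numeric(n); margin <- numeric(n)
  score_rows <- function(model, rows) {
    dm <- xgboost::xgb.DMatrix(X[rows, , drop = FALSE])
    contrib <- predict(model, dm, predcontrib = TRUE)
    values[rows, ] <<- contrib[, seq_len(p), drop = FALSE]
    base[rows] <<- contrib[, p + 1L]
    margin[rows] <<- predict(model, dm, outputmargin = TRUE)
  }
  if (use == "full") {
    score_rows(bundle$full_model, seq_len(n))
  } else {
    for (f in seq_len(bundle$k)) score_rows(bundle$models[[f]],
                                            which(bundle$fold == f))
  }
  structure(list(values = values, base = base, margin = margin,
                 groups = groups),
            class = "shap_matrix")
}

#' Mean-|SHAP| feature importance ranking
#'
#' @param shap A `shap_matrix`.
#' @return Data frame ordered by descending importance: `feature`,
#'   `importance` (mean absolute attribution).
#' @export
importance_ranking <- function(shap) {
  imp <- colMeans(abs(shap$values))
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Per-individual SHAP interaction tensors
#'
#' Symmetric per-individual feature-by-feature decomposition of the
#' attributions (diagonal = main effects; off-diagonal pairs sum with the
#' matching attribution row). Exact interaction TreeSHAP is expensive
#' (cost grows with rows x features x trees), so the tensor is computed on
#' a random subsample of individuals capped at `max_rows`; the downstream
#' interaction statistic is a mean over individuals, which the subsample
#' estimates unbiasedly.
#'
#' @param bundle A tree `model_bundle`.
#' @param X Feature matrix.
#' @param max_rows Cap on individuals entering the tensor (default 400).
#' @param use `"full"` (default) or `"oof"` model for attribution.
#' @param seed Seed for the row subsample.
#' @return An `interaction_tensor`: list with `tensor` (m x p x p), `phi`
#'   (matching m x p attribution matrix), `rows` (row indices used),
#'   `features`.
#' @export
compute_interactions <- function(bundle, X, max_rows = 400L,
                                 use = c("full", "oof"), seed = 1L) {
  use <- match.arg(use)
  if (!inherits(bundle, "model_bundle") || bundle$model_type != "gbdt")
    stop_named("SHAP interactions require a tree-ensemble model bundle")
  n <- nrow(X); p <- ncol(X)
  rows <- seq_len(n)
  if (n > max_rows) {
    set.seed(seed)
    rows <- sort(sample.int(n, max_rows))
  }
  tensor <- array(0, dim = c(length(rows), p, p),
                  dimnames = list(NULL, colnames(X), colnames(X)))
  phi <- matrix(0, length(rows), p, dimnames = list(NULL, colnames(X)))
  attribute <- function(model, sub) {
    dm <- xgboost::xgb.DMatrix(X[rows[sub], , drop = FALSE])
    it <- predict(model, dm, predinteraction = TRUE)
    tensor[sub, , ] <<- it[, seq_len(p), seq_len(p), drop = FALSE]
    ph <- predict(model, dm, predcontrib = TRUE)
    phi[sub, ] <<- ph[, seq_len(p), drop = FALSE]
  }
  if (use == "full") {
    attribute(bundle$full_model, seq_along(rows))
  } else {
    for (f in seq_len(bundle$k)) {
      sub <- which(bundle$fold[rows] == f)
      if (length(sub)) attribute(bundle$models[[f]], sub)
    }
  }
  structure(list(tensor = tensor, phi = phi, rows = rows,
                 features = colnames(X)),
            class = "interaction_tensor")
}

#' Significance test for pairwise SHAP interactions
#'
#' Each unordered pair's per-individual value is the sum of its two
#' symmetric tensor entries; the pair statistic is the mean absolute value
#' across individuals (absolute so protective and risk interactions both
#' register; the signed mean is reported alongside). With the default
#' cross-pair background, the statistic is standardized against the
#' distribution of the statistic over all off-diagonal pairs; the
#' `"individuals"` background instead z-tests each pair's signed values
#' against zero across individuals. Two-sided normal p-values with
#' Benjamini-Hochberg FDR correction.
#'
#' @param interactions An `interaction_tensor`.
#' @param groups Optional named feature group labels (`MHC`/`NON_MHC`/...)
#'   used to place each pair into `MHC-MHC`, `MHC-nonMHC` or
#'   `nonMHC-nonMHC` categories.
#' @param background `"pairs"` (default) or `"individuals"`.
#' @return Data frame per unordered pair: `id_a`, `id_b`, `mean_abs`,
#'   `mean_signed`, `z`, `p`, `q`, `category`, ordered by descending `z`.
#' @export
interaction_significance <- function(interactions, groups = NULL,
                                     background = c("pairs", "individuals")) {
  background <- match.arg(background)
  tensor <- interactions$tensor
  p <- dim(tensor)[2]
  if (p < 2) return(data.frame(id_a = character(), id_b = character(),
                               mean_abs = numeric(), mean_signed = numeric(),
                               z = numeric(), p = numeric(), q = numeric(),
                               category = character()))
  feats <- interactions$features
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  vals <- apply(pairs, 1, function(jk)
    tensor[, jk[1], jk[2]] + tensor[, jk[2], jk[1]])
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  mean_abs <- colMeans(abs(vals))
  mean_signed <- colMeans(vals)
  if (background == "pairs") {
    mu <- mean(mean_abs); sdv <- stats::sd(mean_abs)
    z <- if (isTRUE(sdv > 0)) (mean_abs - mu) / sdv else rep(0, length(mean_abs))
  } else {
    sdv <- apply(vals, 2, stats::sd)
    z <- ifelse(sdv > 0, mean_signed / (sdv / sqrt(nrow(vals))), 0)
  }
  pv <- 2 * stats::pnorm(-abs(z))
  category <- rep(NA_character_, nrow(pairs))
  if (!is.null(groups)) {
    ga <- groups[feats[pairs[, 1]]]; gb <- groups[feats[pairs[, 2]]]
    is_mhc <- function(g) g == "MHC"
    category <- ifelse(is_mhc(ga) & is_mhc(gb), "MHC-MHC",
                ifelse(!is_mhc(ga) & !is_mhc(gb), "nonMHC-nonMHC",
                       "MHC-nonMHC"))
  }
  out <- data.frame(id_a = feats[pairs[, 1]], id_b = feats[pairs[, 2]],
                    mean_abs = mean_abs, mean_signed = mean_signed, z = z,
                    p = pv, q = stats::p.adjust(pv, "BH"),
                    category = category, stringsAsFactors = FALSE)
  out[order(-out$z, out$id_a, out$id_b), , drop = FALSE]
}

#' Per-individual complexity scores
#'
#' The total displacement of an individual's attributions: the sum of
#' absolute SHAP values across features. Low scores mean a prediction
#' driven by one or a few strong features; high scores mean many small
#' contributions. Individuals are assigned to balanced deciles.
#'
#' @param shap A `shap_matrix`.
#' @return Data frame: `complexity`, `decile` (1-10, balanced within one).
#' @export
complexity_scores <- function(shap) {
  C <- rowSums(abs(shap$values))
  data.frame(complexity = C, decile = ntile_int(C, 10L))
}

#' Model performance across complexity deciles
#'
#' AUC of each score set within each complexity decile, with the DeLong
#' p-value for the first-versus-second score comparison per decile.
#'
#' @param scores Named list of score vectors (first entry is the reference
#'   model).
#' @param labels 0/1 labels.
#' @param deciles Integer decile assignment (e.g. from
#'   [complexity_scores()]).
#' @return Data frame: `decile`, one AUC column per model, `delta`,
#'   `delong_p` for the first pair.
#' @export
performance_by_complexity <- function(scores, labels, deciles) {
  stopifnot(is.list(scores), length(scores) >= 1)
  nm <- names(scores) %||% paste0("model", seq_along(scores))
  rows <- lapply(sort(unique(deciles)), function(d) {
    i <- deciles == d
    if (length(unique(labels[i])) < 2) return(NULL)
    aucs <- vapply(scores, function(s) auc(s[i], labels[i]), 0)
    row <- data.frame(decile = d)
    for (k in seq_along(aucs)) row[[nm[k]]] <- aucs[[k]]
    if (length(scores) >= 2) {
      dl <- delong_test(scores[[1]][i], scores[[2]][i], labels[i])
      row$delta <- dl$delta; row$delong_p <- dl$p
    }
    row
  })
  do.call(rbind, rows)
}

#' Grouped component attributions by stratum
#'
#' Sums each individual's attributions within feature groups (e.g. MHC vs
#' non-MHC), then summarizes per stratum with a one-sample two-sided t-test
#' against zero.
#'
#' @param shap A `shap_matrix`.
#' @param groups Named feature group labels (defaults to `shap$groups`).
#' @param strata Factor of strata (e.g. DR3/DR4 diplotype class).
#' @return Data frame: `stratum`, `group`, `mean_sum`, `t`, `p`, `n`.
#' @export
component_attribution <- function(shap, groups = NULL, strata) {
  groups <- groups %||% shap$groups
  stopifnot(!is.null(groups))
  groups <- groups[colnames(shap$values)]
  rows <- list()
  for (g in unique(groups)) {
    gs <- rowSums(shap$values[, groups == g, drop = FALSE])
    for (s in levels(factor(strata))) {
      x <- gs[strata == s]
      tt <- if (length(x) > 1 && stats::sd(x) > 0)
        stats::t.test(x) else list(statistic = NA_real_, p.value = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, group = g, mean_sum = mean(x),
        t = unname(tt$statistic), p = tt$p.value, n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Two-dimensional partial dependence surface
#'
#' Mean model output over the cohort with the two features clamped to each
#' combination of the allele-count grid; on the margin scale the
#' interaction contrast `f(2,2) - f(2,0) - f(0,2) + f(0,0)` is zero for a
#' purely additive model.
#'
#' @param bundle A `model_bundle` (the full-data model is used).
#' @param X Feature matrix.
#' @param pair Character vector of the two feature names.
#' @param grid Allele-count grid (default `0:2`).
#' @param output `"margin"` (default) or `"prob"`.
#' @return List: `surface` (grid x grid matrix), `contrast` (corner
#'   interaction contrast on the chosen scale).
#' @export
partial_dependence_2d <- function(bundle, X, pair, grid = 0:2,
                                  output = c("margin", "prob")) {
  output <- match.arg(output)
  stopifnot(length(pair) == 2, all(pair %in% colnames(X)))
  surf <- matrix(NA_real_, length(grid), length(grid),
                 dimnames = list(as.character(grid), as.character(grid)))
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    X2 <- X
    X2[, pair[1]] <- grid[i]
    X2[, pair[2]] <- grid[j]
    pr <- predict(bundle$full_model, xgboost::xgb.DMatrix(X2),
                  outputmargin = (output == "margin"))
    surf[i, j] <- mean(pr)
  }
  g <- as.character(range(grid))
  contrast <- surf[g[2], g[2]] - surf[g[2], g[1]] - surf[g[1], g[2]] +
    surf[g[1], g[1]]
  list(surface = surf, contrast = contrast)
}
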