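#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-cohort effect estimates with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1 / sqrt(sum(w))`.
#'
#' @param results List of `assoc_result` objects (or data frames with
#'   `beta`, `se`, `n`) for the same variant and allele orientation.
#' @return A `meta_result` list: `variant_id`, `beta`, `se`, `z`, `p`,
#'   `n_total`, and the per-cohort inputs.
#' @export
ivw_meta <- function(results) {
  stopifnot(length(results) >= 1)
  ids <- unique(vapply(results, function(r) r$variant_id %||% "x", ""))
  if (length(ids) > 1)
    stop_named("mismatched variants in meta-analysis: %s",
               paste(ids, collapse = ", "))
  beta_i <- vapply(results, `[[`, 0, "beta")
  se_i <- vapply(results, `[[`, 0, "se")
  stopifnot(all(se_i > 0))
  w <- se_i^-2
  beta <- sum(w * beta_i) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  structure(list(variant_id = ids, beta = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 n_total = sum(vapply(results, function(r) r$n %||% NA_real_, 0)),
                 cohorts = data.frame(beta = beta_i, se = se_i)),
            class = "meta_result")
}

# Per-cohort Firth association for one variant with optional extra
# conditioning columns, combined by IVW meta-analysis.
meta_test_variant <- function(cohorts, vid, conditioning = character()) {
  fits <- lapply(cohorts, function(co) {
    covars <- co$covars
    if (length(conditioning)) {
      covars <- cbind(if (!is.null(covars)) as.matrix(covars),
                      co$G[, conditioning, drop = FALSE])
    }
    firth_logistic(co$y, co$G[, vid], covars, variant_id = vid)
  })
  ivw_meta(fits)
}

#' Genome-wide association scan with Firth logistic regression
#'
#' Tests each panel variant against the labels (per cohort, meta-analyzed
#' across cohorts), applying the MAF filter appropriate for the region:
#' 1% inside the MHC analog, 0.1% genome-wide.
#'
#' @param cohorts List of cohorts, each a list with elements `y` (labels),
#'   `G` (dosage matrix) and optional `covars`.
#' @param variant_ids Variants to test (default: all shared columns).
#' @param maf_min Minimum pooled alt-allele MAF; variants below are skipped.
#' @return Data frame: `variant_id`, `beta`, `se`, `z`, `p`, `af`, `n`.
#' @export
assoc_scan <- function(cohorts, variant_ids = NULL, maf_min = 0) {
  stopifnot(length(cohorts) >= 1)
  if (is.null(variant_ids)) variant_ids <- colnames(cohorts[[1]]$G)
  af <- colMeans(do.call(rbind, lapply(cohorts, function(co)
    co$G[, variant_ids, drop = FALSE]))) / 2
  keep <- pmin(af, 1 - af) >= maf_min
  rows <- lapply(variant_ids[keep], function(v) {
    m <- meta_test_variant(cohorts, v)
    data.frame(variant_id = v, beta = m$beta, se = m$se, z = m$z, p = m$p,
               af = af[[v]], n = m$n_total, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-round greedy clumping and locus definition
#'
#' Round 1 clumps by ascending p-value: an index variant must reach
#' `p1` (default 5e-8); members are variants with `p < p2`, `r^2 > r2`
#' with the index and within `kb` kilobases. Round 2 re-clumps the round-1
#' indices, absorbing indices with any LD (`r^2 > 0`) within 500 kb. Each
#' final locus spans +/- 500 kb around its index variant.
#'
#' @param meta Data frame with `variant_id`, `chrom`, `pos`, `p`.
#' @param ld Square r-squared matrix with variant ids as dimnames.
#' @param p1,p2,r2,kb Round-1 clumping parameters.
#' @param locus_kb Half-width of the final locus window (kb).
#' @return Data frame of loci: `index`, `chrom`, `start`, `end`, `p`,
#'   `members` (comma-separated).
#' @export
clump_and_define_loci <- function(meta, ld, p1 = 5e-8, p2 = 0.05, r2 = 0.1,
                                  kb = 10000, locus_kb = 500) {
  stopifnot(all(meta$variant_id %in% rownames(ld)))
  sig <- meta[meta$p < p1, , drop = FALSE]
  if (!nrow(sig)) return(data.frame(index = character(), chrom = character(),
                                    start = integer(), end = integer(),
                                    p = numeric(), members = character()))
  # round 1: greedy clump by ascending p
  cand <- meta[order(meta$p, -abs(meta$p)), ]
  available <- setNames(rep(TRUE, nrow(meta)), meta$variant_id)
  clumps <- list()
  for (i in order(sig$p)) {
    idx <- sig$variant_id[i]
    if (!available[[idx]]) next
    pos_i <- sig$pos[i]; chr_i <- sig$chrom[i]
    memb <- meta$variant_id[
      available[meta$variant_id] & meta$p < p2 & meta$chrom == chr_i &
        abs(meta$pos - pos_i) <= kb * 1000 &
        ld[idx, meta$variant_id] > r2]
    memb <- union(idx, memb)
    available[memb] <- FALSE
    clumps[[idx]] <- list(index = idx, chrom = chr_i, pos = pos_i,
                          p = sig$p[i], members = memb)
  }
  # round 2: merge round-1 indices in any LD within the locus window
  idx_ids <- names(clumps)
  ord <- idx_ids[order(vapply(clumps, `[[`, 0, "p"))]
  merged <- list(); taken <- character()
  for (idx in ord) {
    if (idx %in% taken) next
    ci <- clumps[[idx]]
    absorb <- idx_ids[!idx_ids %in% taken & idx_ids != idx &
                        vapply(idx_ids, function(j)
                          clumps[[j]]$chrom == ci$chrom &&
                            abs(clumps[[j]]$pos - ci$pos) <= locus_kb * 1000 &&
                            ld[idx, j] > 0, TRUE)]
    memb <- unique(c(ci$members, unlist(lapply(absorb, function(j)
      clumps[[j]]$members))))
    taken <- c(taken, idx, absorb)
    merged[[idx]] <- data.frame(
      index = idx, chrom = ci$chrom,
      start = as.integer(ci$pos - locus_kb * 1000),
      end = as.integer(ci$pos + locus_kb * 1000),
      p = ci$p, members = paste(memb, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Stepwise conditional discovery of independent signals
#'
#' Iteratively tests every remaining region variant per cohort with the
#' current conditioning set added to the covariates, meta-analyzes across
#' cohorts, and promotes the most significant variant into the conditioning
#' set; stops when no variant reaches the threshold. Ties break on smallest
#' p, then largest |z|, then lexicographic id. A candidate whose dosage is
#' collinear with the existing set is skipped with a warning.
#'
#' @param cohorts List of cohorts (`y`, `G`, `covars`).
#' @param region Variant ids to scan.
#' @param threshold Inclusion p-value threshold (default 5e-8).
#' @param max_signals Safety cap on discovered signals.
#' @return Data frame of signals: `rank`, `variant_id`, `beta`, `se`, `p`,
#'   `conditioning` (comma-separated ids at inclusion time).
#' @export
stepwise_conditional <- function(cohorts, region, threshold = 5e-8,
                                 max_signals = 20L) {
  stopifnot(length(region) >= 1)
  signals <- list()
  conditioning <- character()
  repeat {
    remaining <- setdiff(region, conditioning)
    if (!length(remaining) || length(signals) >= max_signals) break
    res <- lapply(remaining, function(v) {
      tryCatch(meta_test_variant(cohorts, v, conditioning),
               error = function(e) {
                 warning(sprintf("skipping %s: %s", v, conditionMessage(e)),
                         call. = FALSE)
                 NULL
               })
    })
    keep <- !vapply(res, is.null, TRUE)
    res <- res[keep]; ids <- remaining[keep]
    if (!length(res)) break
    p <- vapply(res, `[[`, 0, "p")
    z <- vapply(res, `[[`, 0, "z")
    ord <- order(p, -abs(z), ids)
    best <- ord[1]
    if (p[best] >= threshold) break
    b <- res[[best]]
    signals[[length(signals) + 1L]] <- data.frame(
      rank = length(signals) + 1L, variant_id = ids[best], beta = b$beta,
      se = b$se, p = b$p,
      conditioning = paste(conditioning, collapse = ","),
      stringsAsFactors = FALSE)
    conditioning <- c(conditioning, ids[best])
  }
  if (!length(signals))
    return(data.frame(rank = integer(), variant_id = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      conditioning = character()))
  do.call(rbind, signals)
}

#' Build HLA preconditioning covariates
#'
#' One dosage column per risk-allele tag plus one binary column per
#' interaction pair, set to 1 iff the individual carries at least one copy
#' of both pair members — the covariate block used to precondition the
#' conditional scan on established MHC risk alleles and their interactions.
#'
#' @param G Dosage matrix.
#' @param alleles Character vector of tag variant ids.
#' @param interactions Data frame (or 2-column matrix) of id pairs.
#' @return Numeric matrix with `length(alleles) + nrow(interactions)` columns.
#' @export
build_precondition_covariates <- function(G, alleles,
                                          interactions = NULL) {
  unknown <- setdiff(alleles, colnames(G))
  if (length(unknown))
    stop_named("unknown allele tags: %s", paste(unknown, collapse = ", "))
  M <- G[, alleles, drop = FALSE]
  colnames(M) <- paste0("allele_", alleles)
  if (!is.null(interactions) && nrow(interactions)) {
    ia <- as.matrix(interactions)[, 1:2, drop = FALSE]
    unknown <- setdiff(as.vector(ia), colnames(G))
    if (length(unknown))
      stop_named("unknown interaction tags: %s", paste(unknown, collapse = ", "))
    B <- sapply(seq_len(nrow(ia)), function(r)
      as.numeric(G[, ia[r, 1]] >= 1 & G[, ia[r, 2]] >= 1))
    colnames(B) <- paste0("pair_", ia[, 1], "_", ia[, 2])
    M <- cbind(M, B)
  }
  M
}
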