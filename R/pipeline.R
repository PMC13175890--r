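# End-to-end orchestration: simulate -> associate -> fine-map -> train ->
# interpret -> subtype, from a single validated config with one master seed.

#' Default pipeline configuration
#'
#' A demo-scale configuration exercising every stage: a 60-variant panel
#' with an MHC-analog block, planted additive, haplotype and epistatic
#' effects, four clinical subtypes, and the model/cluster parameters used
#' throughout (254 trees, depth 5, learning rate 0.12; Leiden resolution
#' 0.05).
#'
#' @param n Cohort size.
#' @param n_variants Panel size.
#' @param seed Master seed.
#' @return A nested configuration list for [run_pipeline()].
#' @export
default_config <- function(n = 5000L, n_variants = 60L, seed = 1L) {
  list(
    seed = seed,
    simulate = list(
      n = n, n_variants = n_variants, n_blocks = 6L, n_mhc = 12L,
      ld_rho = 0.4, n_cohorts = 2L, prevalence = 0.2,
      mhc = list(freq = c(DR3 = 0.15, DR4 = 0.15, X = 0.70),
                 log_or = c(DR3 = log(2.2), DR4 = log(2.2), X = 0),
                 het_bonus = log(16 / 2.2^2)),
      n_additive = 12L, additive_sd = 0.25,
      interactions = 2L, interaction_log_or = 0.7,
      subtypes = c(s1 = 0.25, s2 = 0.25, s3 = 0.25, s4 = 0.25),
      onset_shift = c(s1 = 10, s2 = 12, s3 = 15, s4 = 18),
      cvd_multiplier = c(s1 = 1, s2 = 1, s3 = 1.46, s4 = 1)),
    assoc = list(maf_min = 0.001, threshold = 5e-8),
    finemap = list(w = 0.04, mass = 0.95, r2_threshold = 0.1),
    train = list(k = 10L, trees = 254L, depth = 5L, lr = 0.12,
                 l2_c = 0.001, with_covars = TRUE),
    interpret = list(max_rows = 200L, fdr = 0.05),
    subtype = list(n_pcs = 175L, k = 120L, resolution = 0.05),
    stages = list(simulate = TRUE, assoc = TRUE, finemap = TRUE,
                  train = TRUE, interpret = TRUE, subtype = TRUE)
  )
}

# Schema check: every required key present with the right type; offending
# keys are listed together in the rejection message.
validate_config <- function(config) {
  problems <- character()
  need <- function(path, test) {
    v <- config
    for (k in strsplit(path, "$", fixed = TRUE)[[1]]) v <- v[[k]]
    if (is.null(v) || !test(v)) problems <<- c(problems, path)
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1
  need("seed", num1)
  need("simulate$n", function(v) num1(v) && v >= 100)
  need("simulate$n_variants", function(v) num1(v) && v >= 10)
  need("simulate$prevalence", function(v) num1(v) && v > 0 && v < 1)
  need("assoc$threshold", function(v) num1(v) && v > 0 && v < 1)
  need("finemap$w", function(v) num1(v) && v > 0)
  need("finemap$mass", function(v) num1(v) && v > 0 && v < 1)
  need("train$k", function(v) num1(v) && v >= 2)
  need("subtype$resolution", num1)
  need("stages", is.list)
  if (length(problems))
    stop_named("invalid pipeline config; offending keys: %s",
               paste(problems, collapse = ", "))
  invisible(config)
}

pipeline_cohort_list <- function(cohort) {
  s <- cohort$samples
  covars <- as.matrix(s[, c("sex", "PC1", "PC2", "PC3", "PC4")])
  lapply(sort(unique(s$cohort)), function(cc) {
    i <- s$cohort == cc
    list(y = s$label[i], G = cohort$dosage[i, , drop = FALSE],
         covars = covars[i, , drop = FALSE])
  })
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order, each writing its outputs before the
#' next starts; disabled stages are skipped along with their outputs. A
#' manifest with per-stage output hashes, wall times and seeds is written
#' to `manifest.json`, and re-running with the same config and seed
#' reproduces identical hashes for the deterministic stages.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(seed = seed, stages = list())
  log_stage <- function(name, t0, files) {
    manifest$stages[[name]] <<- list(
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
      outputs = as.list(tools::md5sum(files[file.exists(files)])))
    message(sprintf("[%s] done (%.1fs)", name,
                    as.numeric(Sys.time()) - t0))
  }
  st <- config$stages
  cohort <- NULL; meta <- NULL; bundle <- NULL; shap <- NULL; feats <- NULL

  if (isTRUE(st$simulate)) {
    t0 <- as.numeric(Sys.time())
    sc <- config$simulate
    set.seed(child_seed(seed, "panel"))
    panel <- variant_panel(sc$n_variants, n_blocks = sc$n_blocks,
                           maf = stats::runif(sc$n_variants, 0.05, 0.5),
                           n_mhc = sc$n_mhc)
    mhc <- mhc_spec(freq = sc$mhc$freq,
                    tags = list(DR3 = panel$id[1], DR4 = panel$id[2],
                                X = panel$id[3]),
                    log_or = sc$mhc$log_or, het_bonus = sc$mhc$het_bonus)
    set.seed(child_seed(seed, "effects"))
    free <- panel$id[panel$group == "NON_MHC"]
    add_ids <- sample(free, sc$n_additive)
    additive <- stats::setNames(abs(stats::rnorm(sc$n_additive,
                                                 sd = sc$additive_sd)),
                                add_ids)
    ints <- NULL
    if (sc$interactions > 0) {
      ia <- panel$id[seq_len(sc$interactions)]          # MHC tags
      ib <- sample(setdiff(free, add_ids), sc$interactions)
      ints <- data.frame(id_a = ia, id_b = ib,
                         log_or = sc$interaction_log_or)
    }
    effects <- effect_spec(additive = additive, interactions = ints,
                           intercept = qlogis(sc$prevalence) -
                             sum(additive) * 0.5,
                           covariate_betas = c(sex = 0.1))
    clinical <- clinical_spec(
      onset = data.frame(subtype = names(sc$subtypes),
                         location = sc$onset_shift, scale = 6),
      odds_multiplier = local({
        m <- matrix(1, length(sc$subtypes), 4,
                    dimnames = list(names(sc$subtypes),
                                    c("nephropathy", "neuropathy", "cvd",
                                      "retinopathy")))
        m[names(sc$cvd_multiplier), "cvd"] <- sc$cvd_multiplier
        m
      }))
    cohort <- simulate_cohort(sc$n, panel, effects, mhc = mhc,
                              clinical = clinical,
                              subtype_prop = sc$subtypes,
                              ld_rho = sc$ld_rho, n_cohorts = sc$n_cohorts,
                              seed = seed)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    log_stage("simulate", t0,
              file.path(out_dir, "cohort",
                        c("genotypes.vcf", "samples.tsv", "truth.json")))
  }

  if (isTRUE(st$assoc)) {
    if (is.null(cohort)) stop_named("assoc stage requires the simulate stage")
    t0 <- as.numeric(Sys.time())
    cl <- pipeline_cohort_list(cohort)
    meta <- assoc_scan(cl, maf_min = config$assoc$maf_min)
    meta$chrom <- cohort$panel$chrom[match(meta$variant_id, cohort$panel$id)]
    meta$pos <- cohort$panel$pos[match(meta$variant_id, cohort$panel$id)]
    f <- file.path(out_dir, "summary_stats.tsv")
    utils::write.table(meta, f, sep = "\t", row.names = FALSE, quote = FALSE)
    message(sprintf("[assoc] %d variants tested, %d at p<%g",
                    nrow(meta), sum(meta$p < config$assoc$threshold),
                    config$assoc$threshold))
    log_stage("assoc", t0, f)
  }

  if (isTRUE(st$finemap)) {
    if (is.null(meta)) stop_named("finemap stage requires the assoc stage")
    t0 <- as.numeric(Sys.time())
    lead <- meta$variant_id[which.min(meta$p)]
    ld <- stats::cor(cohort$dosage)^2
    ls <- linkage_set(lead, ld, config$finemap$r2_threshold)
    i <- match(ls, meta$variant_id)
    cs <- credible_set(ls, log_bf = wakefield_bf(meta$beta[i], meta$se[i],
                                                 config$finemap$w, log = TRUE),
                       mass = config$finemap$mass)
    cs$signal <- lead
    f <- file.path(out_dir, "credible_sets.tsv")
    utils::write.table(cs, f, sep = "\t", row.names = FALSE, quote = FALSE)
    log_stage("finemap", t0, f)
  }

  if (isTRUE(st$train)) {
    if (is.null(cohort)) stop_named("train stage requires the simulate stage")
    t0 <- as.numeric(Sys.time())
    tc <- config$train
    betas <- if (!is.null(meta)) stats::setNames(meta$beta, meta$variant_id)
    feats <- assemble_features(cohort, betas = betas, submodel = "ALL",
                               with_covars = isTRUE(tc$with_covars))
    y <- cohort$samples$label
    bundle <- train_gbdt_cv(feats$X, y, k = tc$k,
                            params = list(trees = tc$trees, depth = tc$depth,
                                          lr = tc$lr),
                            seed = child_seed(seed, "train"))
    lr <- train_logreg_cv(feats$X, y, l2_c = tc$l2_c, k = tc$k,
                          seed = child_seed(seed, "train"))
    scores <- data.frame(sample_id = cohort$samples$sample_id,
                         submodel = "ALL", oof_score = bundle$oof,
                         oof_logreg = lr$oof)
    utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    dl <- delong_test(bundle$oof, lr$oof, y)
    eval_out <- list(auc_gbdt = auc(bundle$oof, y),
                     ap_gbdt = average_precision(bundle$oof, y),
                     auc_logreg = auc(lr$oof, y),
                     delong_p = dl$p)
    jsonlite::write_json(eval_out, file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(youden_scale(bundle$oof, y),
                       file.path(out_dir, "score_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    attr(bundle, "logreg") <- lr
    log_stage("train", t0, file.path(out_dir, c("scores.tsv", "eval.json",
                                                "score_table.tsv")))
  }

  if (isTRUE(st$interpret)) {
    if (is.null(bundle)) stop_named("interpret stage requires the train stage")
    t0 <- as.numeric(Sys.time())
    shap <- compute_shap(bundle, feats$X, use = "oof", groups = feats$groups)
    utils::write.table(importance_ranking(shap),
                       file.path(out_dir, "importance.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    it <- compute_interactions(bundle, feats$X,
                               max_rows = config$interpret$max_rows,
                               seed = child_seed(seed, "interactions"))
    sig <- interaction_significance(it, groups = feats$groups)
    utils::write.table(sig, file.path(out_dir, "interactions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cbind(sample_id = cohort$samples$sample_id,
                             complexity_scores(shap)),
                       file.path(out_dir, "complexity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    log_stage("interpret", t0,
              file.path(out_dir, c("importance.tsv", "interactions.tsv",
                                   "complexity.tsv")))
  }

  if (isTRUE(st$subtype)) {
    if (is.null(shap)) stop_named("subtype stage requires the interpret stage")
    t0 <- as.numeric(Sys.time())
    cases <- cohort$samples$label == 1
    emb <- embed_shap(shap$values[cases, , drop = FALSE],
                      n_pcs = config$subtype$n_pcs, k = config$subtype$k)
    ca <- cluster_shap(emb, resolution = config$subtype$resolution,
                       seed = child_seed(seed, "leiden"))
    sil <- if (ca$k >= 2)
      cluster::silhouette(ca$labels, stats::dist(emb$pcs))[, "sil_width"]
    else rep(NA_real_, sum(cases))
    clusters <- data.frame(sample_id = cohort$samples$sample_id[cases],
                           cluster = ca$labels, silhouette = sil)
    utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report <- list(k = ca$k, resolution = ca$resolution,
                   sizes = as.integer(table(ca$labels)))
    onset <- cohort$samples$onset_age[cases]
    if (ca$k >= 2 && any(!is.na(onset))) {
      lr0 <- onset_logrank(onset, ca$labels)
      report$onset_logrank_p <- lr0$overall$p
      report$median_onset <- lr0$per_cluster$median_onset
      cvd <- cohort$samples$cvd[cases]
      report$cvd_or <- lapply(seq_len(ca$k), function(c0) {
        ca0 <- complication_assoc(cvd, ca$labels, c0)
        list(cluster = c0, or = ca0$or, ci = ca0$ci, p = ca0$p)
      })
    }
    jsonlite::write_json(report, file.path(out_dir, "cluster_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("subtype", t0, file.path(out_dir, c("clusters.tsv",
                                                  "cluster_report.json")))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a human-readable run report
#'
#' Summarizes a pipeline run directory: the Youden score table, the
#' significant interaction pairs (or "none significant"), and the cluster
#' report. Regeneration is idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param fdr Interaction significance threshold on q.
#' @return Path of the written `report.txt`, invisibly.
#' @export
make_report <- function(run_dir, fdr = 0.05) {
  lines <- c("t1grslab run report", strrep("=", 40))
  st_path <- file.path(run_dir, "score_table.tsv")
  if (file.exists(st_path)) {
    st <- utils::read.delim(st_path)
    lines <- c(lines, "", "Diagnostic scale (Youden index by case centile):",
               sprintf("  centile %2d: threshold %.4f sens %.1f%% spec %.1f%% J %.4f",
                       st$case_centile, st$threshold, st$sensitivity,
                       st$specificity, st$youden))
  }
  it_path <- file.path(run_dir, "interactions.tsv")
  if (file.exists(it_path)) {
    it <- utils::read.delim(it_path)
    sig <- it[it$q < fdr, , drop = FALSE]
    lines <- c(lines, "", sprintf("Significant interactions (q < %g):", fdr))
    lines <- c(lines, if (nrow(sig))
      sprintf("  %s x %s (z = %.2f, q = %.3g)", sig$id_a, sig$id_b, sig$z,
              sig$q)
      else "  none significant")
  }
  cr_path <- file.path(run_dir, "cluster_report.json")
  if (file.exists(cr_path)) {
    cr <- jsonlite::read_json(cr_path, simplifyVector = TRUE)
    lines <- c(lines, "", sprintf("Clusters: k = %d (sizes %s)", cr$k,
                                  paste(cr$sizes, collapse = ", ")))
    if (!is.null(cr$onset_logrank_p))
      lines <- c(lines, sprintf("  onset log-rank p = %.3g; median onsets: %s",
                                cr$onset_logrank_p,
                                paste(round(cr$median_onset, 1),
                                      collapse = ", ")))
  }
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
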