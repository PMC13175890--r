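#!/usr/bin/env Rscript

# Stage 5: SHAP interpretation of the tree model.
#
# Out-of-fold SHAP attributions, mean-|SHAP| feature importance, pairwise
# SHAP interaction tests (cross-pair z with BH correction, grouped into
# MHC/non-MHC categories), per-individual complexity scores, and per-decile
# model-performance deltas. Writes importance.tsv, interactions.tsv,
# complexity.tsv, performance_by_complexity.tsv, component_attribution.tsv.

suppressPackageStartupMessages(library(t1grslab))

out <- "results"
seed <- 20260105L
cohort <- readRDS(file.path(out, "cache", "cohort.rds"))
models <- readRDS(file.path(out, "cache", "models.rds"))
y <- cohort$samples$label

shap <- compute_shap(models$gb, models$feats$X, use = "oof",
                     groups = models$feats$groups)
write.table(importance_ranking(shap), file.path(out, "importance.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

it <- compute_interactions(models$gb, models$feats$X, max_rows = 400L,
                           seed = child_seed(seed, "interactions"))
sig <- interaction_significance(it, groups = models$feats$groups)
write.table(sig, file.path(out, "interactions.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("%d significant interaction pairs at q < 0.05 (top: %s x %s)",
                sum(sig$q < 0.05), sig$id_a[1], sig$id_b[1]))

cx <- complexity_scores(shap)
write.table(cbind(sample_id = cohort$samples$sample_id, cx),
            file.path(out, "complexity.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
perf <- performance_by_complexity(list(gbdt = models$gb$oof,
                                       logreg = models$lr$oof),
                                  y, cx$decile)
write.table(perf, file.path(out, "performance_by_complexity.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

comp <- component_attribution(shap, strata = as.character(cohort$mhc_class))
write.table(comp, file.path(out, "component_attribution.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
saveRDS(shap, file.path(out, "cache", "shap.rds"))
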