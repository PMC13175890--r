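#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# A 5,000-individual case-control cohort over 60 variants in 6 LD blocks,
# with an MHC-analog region (DR3/DR4-style haplotype classes with a
# heterozygote bonus), a polygenic additive background, two planted
# MHC x non-MHC interactions, and clinical outcomes (onset age plus
# complications with a planted CVD odds multiplier for subtype s1).
#
# Writes results/cohort/ (VCF + samples.tsv + truth.json) and caches the
# in-memory cohort object for the downstream stages.

suppressPackageStartupMessages(library(t1grslab))

seed <- 20260101L
out <- "results"
dir.create(file.path(out, "cache"), recursive = TRUE, showWarnings = FALSE)

panel <- variant_panel(60, n_blocks = 6L, n_mhc = 8L,
                       maf = withr::with_seed(child_seed(seed, "panel"),
                                              runif(60, 0.05, 0.5)))
mhc <- mhc_spec(freq = c(DR3 = 0.15, DR4 = 0.15, X = 0.70),
                tags = list(DR3 = "var001", DR4 = "var002", X = "var003"),
                log_or = c(DR3 = 0.4, DR4 = 0.4, X = 0),
                het_bonus = log(4))
additive <- withr::with_seed(
  child_seed(seed, "effects"),
  setNames(abs(rnorm(20, sd = 0.25)) + 0.05,
           sample(panel$id[panel$group == "NON_MHC"], 20)))
interactions <- data.frame(id_a = c("var001", "var002"),
                           id_b = setdiff(panel$id[panel$group == "NON_MHC"],
                                          names(additive))[1:2],
                           log_or = 0.8)
effects <- effect_spec(additive = additive, interactions = interactions,
                       intercept = qlogis(0.3) - sum(additive) * 0.5,
                       covariate_betas = c(sex = 0.1),
                       encoding = "carrier")
clinical <- clinical_spec(
  onset = data.frame(subtype = c("s1", "s2", "s3"),
                     location = c(16, 11, 11), scale = 5),
  odds_multiplier = matrix(c(rep(1, 8), 1.46, 1, 1, 1), 3, 4,
                           dimnames = list(c("s1", "s2", "s3"),
                                           c("nephropathy", "neuropathy",
                                             "cvd", "retinopathy"))))

cohort <- simulate_cohort(5000, panel, effects, mhc = mhc,
                          clinical = clinical,
                          subtype_prop = c(s1 = 0.3, s2 = 0.4, s3 = 0.3),
                          ld_rho = 0.5, n_cohorts = 2L, seed = seed)

write_cohort(cohort, file.path(out, "cohort"))
saveRDS(cohort, file.path(out, "cache", "cohort.rds"))
message(sprintf("simulated %d individuals (%d cases) over %d variants",
                nrow(cohort$samples), sum(cohort$samples$label),
                nrow(cohort$panel)))
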