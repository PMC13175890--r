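#!/usr/bin/env Rscript

# Stage 2: per-cohort Firth association scan, fixed-effects IVW meta,
# two-round clumping with locus definition, and stepwise conditional
# analysis within the strongest locus.
#
# Reads results/cache/cohort.rds (stage 1); writes summary_stats.tsv,
# loci.tsv, and conditional_signals.tsv under results/.

suppressPackageStartupMessages(library(t1grslab))

out <- "results"
cohort <- readRDS(file.path(out, "cache", "cohort.rds"))
cohorts <- t1grslab:::pipeline_cohort_list(cohort)

meta <- assoc_scan(cohorts, maf_min = 0.01)
meta$chrom <- cohort$panel$chrom[match(meta$variant_id, cohort$panel$id)]
meta$pos <- cohort$panel$pos[match(meta$variant_id, cohort$panel$id)]
write.table(meta, file.path(out, "summary_stats.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("%d variants tested; %d genome-wide significant",
                nrow(meta), sum(meta$p < 5e-8)))

ld <- cor(cohort$dosage)^2
loci <- clump_and_define_loci(meta, ld)
write.table(loci, file.path(out, "loci.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("%d loci after clumping", nrow(loci)))

if (nrow(loci) > 0) {
  top <- loci[which.min(meta$p[match(loci$index, meta$variant_id)]), ]
  region <- strsplit(top$members, ",")[[1]]
  signals <- stepwise_conditional(cohorts, region, threshold = 5e-8)
  write.table(signals, file.path(out, "conditional_signals.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  message(sprintf("%d independent signals in locus %s",
                  nrow(signals), top$index))
}
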