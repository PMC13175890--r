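#' Write a cohort to disk (VCF + TSV + JSON)
#'
#' Genotypes go to `genotypes.vcf` (VCF v4.2, unphased GT, one sample per
#' individual), the sample table with covariates, labels and clinical
#' outcomes to `samples.tsv`, and the truth record (planted specs, subtypes,
#' seed) to `truth.json`.
#'
#' @param cohort A `cohort_data` object from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (nrow(cohort$dosage) == 0L) stop_named("refusing to write an empty cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- cohort$panel
  gt <- matrix(c("0/0", "0/1", "1/1")[t(cohort$dosage) + 1L],
               nrow = ncol(cohort$dosage))
  body <- paste(panel$chrom, panel$pos, panel$id, panel$ref, panel$alt,
                ".", "PASS",
                sprintf("BLOCK=%d;GROUP=%s", panel$block_id, panel$group),
                "GT", apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=t1grslab",
    "##INFO=<ID=BLOCK,Number=1,Type=Integer,Description=\"LD block\">",
    "##INFO=<ID=GROUP,Number=1,Type=String,Description=\"MHC or NON_MHC\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t"))
  writeLines(c(header, body), file.path(dir, "genotypes.vcf"))
  samples <- cohort$samples
  samples$mhc_class <- if (!is.null(cohort$mhc_class))
    as.character(cohort$mhc_class) else NA_character_
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$panel <- panel
  jsonlite::write_json(serialize_truth(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

serialize_truth <- function(truth) {
  tr <- truth
  tr$effects <- unclass(tr$effects)
  if (!is.null(tr$mhc)) tr$mhc <- unclass(tr$mhc)
  if (!is.null(tr$clinical)) tr$clinical <- unclass(tr$clinical)
  tr
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()]: parses the VCF with `vcfR`, validates the GT
#' field, and reassembles the `cohort_data` structure. Malformed genotype
#' entries raise an error naming the offending VCF record.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `cohort_data` object.
#' @export
read_cohort <- function(dir) {
  vcf_path <- file.path(dir, "genotypes.vcf")
  if (!file.exists(vcf_path)) stop_named("no genotypes.vcf under %s", dir)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop_named("VCF parse failure in %s: %s",
                                                 vcf_path, conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt[, -1, drop = FALSE]
  bad <- which(matrix(!(gt %in% c("0/0", "0/1", "1/1")), nrow(gt)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop_named("malformed GT at variant %s, sample column %d: '%s'",
               fix$ID[bad[1, 1]], bad[1, 2], gt[bad[1, 1], bad[1, 2]])
  dosage <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow = nrow(gt))
  dosage <- t(dosage)
  colnames(dosage) <- fix$ID
  storage.mode(dosage) <- "integer"
  info <- fix$INFO
  block <- as.integer(sub(".*BLOCK=([0-9]+).*", "\\1", info))
  group <- sub(".*GROUP=([A-Z_]+).*", "\\1", info)
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  panel <- data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      maf = truth$panel$maf, block_id = block, group = group,
                      annotation = truth$panel$annotation %||% NA_character_,
                      stringsAsFactors = FALSE)
  mhc_class <- NULL
  if ("mhc_class" %in% names(samples) && !all(is.na(samples$mhc_class)))
    mhc_class <- factor(samples$mhc_class,
                        levels = c("DR3/DR4", "DR3/DR3 or DR4/DR4",
                                   "one DR3 or DR4", "none"))
  samples$mhc_class <- NULL
  structure(list(dosage = dosage, panel = panel, samples = samples,
                 mhc_class = mhc_class, haplotypes = NULL, mhc_copies = NULL,
                 truth = truth),
            class = "cohort_data")
}
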