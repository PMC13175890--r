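#' Construct and validate a variant panel
#'
#' A panel is a data frame of variant metadata for the simulated genotyping
#' array: identifier, position, alleles, minor-allele frequency, LD block and
#' locus group (`"MHC"` for variants inside the MHC-analog region, `"NON_MHC"`
#' otherwise). An optional `annotation` column carries a synthetic cell-type
#' label used by the regulatory-enrichment analysis.
#'
#' @param n_variants Number of variants.
#' @param n_blocks Number of LD blocks (variants are split evenly).
#' @param maf Vector of minor-allele frequencies, recycled to `n_variants`;
#'   each must lie in (0, 0.5].
#' @param n_mhc Number of leading variants labelled as MHC-analog.
#' @param chrom Chromosome label.
#' @param annotation Optional character vector of cell-type labels.
#' @return A `data.frame` with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf`, `block_id`, `group`, `annotation`.
#' @export
variant_panel <- function(n_variants, n_blocks = 1L, maf = 0.3, n_mhc = 0L,
                          chrom = "6", annotation = NA_character_) {
  stopifnot(n_variants >= 1, n_blocks >= 1, n_mhc >= 0, n_mhc <= n_variants)
  maf <- rep_len(maf, n_variants)
  panel <- data.frame(
    id = sprintf("var%03d", seq_len(n_variants)),
    chrom = chrom,
    pos = 1e6L + 5000L * seq_len(n_variants),
    ref = "A", alt = "G",
    maf = maf,
    block_id = as.integer(ceiling(seq_len(n_variants) / (n_variants / n_blocks))),
    group = c(rep("MHC", n_mhc), rep("NON_MHC", n_variants - n_mhc)),
    annotation = rep_len(annotation, n_variants),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  req <- c("id", "chrom", "pos", "ref", "alt", "maf", "block_id", "group")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols))
    stop_named("panel is missing columns: %s", paste(missing_cols, collapse = ", "))
  dup <- panel$id[duplicated(panel$id)]
  if (length(dup))
    stop_named("duplicate variant ids in panel: %s", paste(unique(dup), collapse = ", "))
  if (any(panel$maf <= 0 | panel$maf > 0.5))
    stop_named("maf must lie in (0, 0.5]; offending ids: %s",
               paste(panel$id[panel$maf <= 0 | panel$maf > 0.5], collapse = ", "))
  for (ch in unique(panel$chrom)) {
    p <- panel$pos[panel$chrom == ch]
    if (any(diff(p) <= 0))
      stop_named("positions must be strictly increasing within chromosome %s", ch)
  }
  invisible(panel)
}

#' Specify the MHC-analog haplotype locus
#'
#' The MHC analog carries three haplotype classes mirroring the high-risk
#' HLA haplotypes: DR3 (DR3-DQ2 analog), DR4 (DR4-DQ8 analog) and X (all
#' others). Each haplotype has one or more tag variants whose dosage equals
#' the haplotype copy count, a per-copy log odds ratio, and DR3/DR4
#' heterozygotes receive an extra `het_bonus` on the log-odds scale — the
#' super-additive risk of inheriting both haplotypes together.
#'
#' @param freq Named numeric vector of haplotype frequencies for
#'   `DR3`, `DR4`, `X`; must sum to 1.
#' @param tags Named list mapping each haplotype to its tag variant id(s).
#' @param log_or Named numeric vector of per-copy log odds ratios.
#' @param het_bonus Extra log-OR applied only to DR3/DR4 heterozygotes.
#' @return An object of class `mhc_spec`.
#' @export
mhc_spec <- function(freq = c(DR3 = 0.15, DR4 = 0.15, X = 0.70),
                     tags = list(DR3 = "var001", DR4 = "var002", X = "var003"),
                     log_or = c(DR3 = 0, DR4 = 0, X = 0),
                     het_bonus = 0) {
  stopifnot(setequal(names(freq), c("DR3", "DR4", "X")),
            abs(sum(freq) - 1) < 1e-8, all(freq >= 0))
  if (!all(lengths(tags[c("DR3", "DR4", "X")]) >= 1))
    stop_named("each haplotype needs at least one tag variant")
  structure(list(freq = freq[c("DR3", "DR4", "X")], tags = tags,
                 log_or = log_or, het_bonus = het_bonus),
            class = "mhc_spec")
}

#' Specify planted genetic and covariate effects
#'
#' @param additive Named numeric vector: variant id -> log odds ratio.
#' @param interactions Data frame with columns `id_a`, `id_b`, `log_or`
#'   (pairwise epistatic terms), or `NULL`.
#' @param intercept Baseline logit (e.g. `qlogis(0.1)` for 10% prevalence
#'   in a null model).
#' @param covariate_betas Named numeric vector of covariate log-ORs
#'   (names must match sample-table columns, e.g. `sex`, `PC1`).
#' @param encoding Interaction encoding: `"dosage"` multiplies alt dosages
#'   (multiplicative on the log-odds scale), `"carrier"` multiplies carrier
#'   indicators (dominance-style).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(additive = numeric(), interactions = NULL,
                        intercept = qlogis(0.1), covariate_betas = numeric(),
                        encoding = c("dosage", "carrier")) {
  encoding <- match.arg(encoding)
  if (!is.null(interactions))
    stopifnot(all(c("id_a", "id_b", "log_or") %in% names(interactions)))
  structure(list(additive = additive, interactions = interactions,
                 intercept = intercept, covariate_betas = covariate_betas,
                 encoding = encoding),
            class = "effect_spec")
}

#' Specify per-subtype clinical outcome distributions
#'
#' @param onset Data frame with columns `subtype`, `location`, `scale`:
#'   per-subtype age-of-onset as a normal truncated at zero (years).
#' @param base_prob Named numeric vector of baseline complication
#'   probabilities for `nephropathy`, `neuropathy`, `cvd`, `retinopathy`.
#' @param odds_multiplier Matrix (subtype x complication) of odds
#'   multipliers applied to the baseline on the odds scale; defaults to 1.
#' @return An object of class `clinical_spec`.
#' @export
clinical_spec <- function(onset,
                          base_prob = c(nephropathy = 0.15, neuropathy = 0.15,
                                        cvd = 0.12, retinopathy = 0.20),
                          odds_multiplier = NULL) {
  stopifnot(all(c("subtype", "location", "scale") %in% names(onset)),
            all(onset$scale > 0),
            all(base_prob > 0 & base_prob < 1))
  comps <- names(base_prob)
  if (is.null(odds_multiplier)) {
    odds_multiplier <- matrix(1, nrow(onset), length(comps),
                              dimnames = list(onset$subtype, comps))
  }
  stopifnot(all(rownames(odds_multiplier) %in% onset$subtype),
            all(odds_multiplier > 0))
  structure(list(onset = onset, base_prob = base_prob,
                 odds_multiplier = odds_multiplier),
            class = "clinical_spec")
}

#' Simulate diploid dosage genotypes with block LD
#'
#' Haplotypes are drawn through a per-block Gaussian copula with an
#' exchangeable latent correlation `ld_rho`: within a block, every pair of
#' variants shares the same latent correlation, which maps monotonically to
#' pairwise genotype r-squared. The two haplotypes are independent, so
#' columns are Hardy-Weinberg binomial(2, maf) marginally.
#'
#' @param panel Variant panel (see [variant_panel()]).
#' @param n Number of individuals.
#' @param ld_rho Latent within-block correlation in `[0, 1)`; scalar or one
#'   value per block.
#' @param seed Integer seed.
#' @return Integer matrix `n x n_variants` of dosages in `{0, 1, 2}`, with
#'   variant ids as column names.
#' @export
simulate_genotypes <- function(panel, n, ld_rho = 0, seed = 1L) {
  validate_panel(panel)
  stopifnot(n >= 1, all(ld_rho >= 0), all(ld_rho < 1))
  blocks <- sort(unique(panel$block_id))
  ld_rho <- rep_len(ld_rho, length(blocks))
  set.seed(seed)
  G <- matrix(0L, n, nrow(panel), dimnames = list(NULL, panel$id))
  for (hap in 1:2) {
    for (bi in seq_along(blocks)) {
      idx <- which(panel$block_id == blocks[bi])
      rho <- ld_rho[bi]
      u <- rnorm(n)
      z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * length(idx)), n)
      thr <- qnorm(panel$maf[idx])
      a <- sweep(z, 2, thr, `<`)
      G[, idx] <- G[, idx] + a
    }
  }
  storage.mode(G) <- "integer"
  G
}

#' Assign MHC-analog diplotypes and overwrite tag-variant dosages
#'
#' Two haplotypes per individual are drawn independently from the haplotype
#' frequencies (Hardy-Weinberg). Tag-variant dosages in the genotype matrix
#' are replaced by the corresponding haplotype copy counts, and each
#' individual receives one of four diplotype classes mirroring the clinical
#' DR3/DR4 stratification.
#'
#' @param G Dosage matrix from [simulate_genotypes()].
#' @param mhc An [mhc_spec()].
#' @param seed Integer seed.
#' @return List with elements `G` (updated matrix), `haplotypes` (n x 2
#'   character matrix) and `class` (factor with levels `"DR3/DR4"`,
#'   `"DR3/DR3 or DR4/DR4"`, `"one DR3 or DR4"`, `"none"`).
#' @export
assign_mhc <- function(G, mhc, seed = 1L) {
  stopifnot(inherits(mhc, "mhc_spec"))
  missing_tags <- setdiff(unlist(mhc$tags), colnames(G))
  if (length(missing_tags))
    stop_named("tag variants not in genotype matrix: %s",
               paste(missing_tags, collapse = ", "))
  n <- nrow(G)
  set.seed(seed)
  haps <- matrix(sample(names(mhc$freq), 2 * n, replace = TRUE, prob = mhc$freq),
                 n, 2)
  copies <- sapply(c("DR3", "DR4", "X"), function(h) rowSums(haps == h))
  for (h in names(mhc$tags))
    for (tag in mhc$tags[[h]]) G[, tag] <- as.integer(copies[, h])
  cls <- ifelse(copies[, "DR3"] >= 1 & copies[, "DR4"] >= 1, "DR3/DR4",
         ifelse(copies[, "DR3"] == 2 | copies[, "DR4"] == 2, "DR3/DR3 or DR4/DR4",
         ifelse(copies[, "DR3"] + copies[, "DR4"] == 1, "one DR3 or DR4", "none")))
  cls <- factor(cls, levels = c("DR3/DR4", "DR3/DR3 or DR4/DR4",
                                "one DR3 or DR4", "none"))
  list(G = G, haplotypes = haps, class = cls, copies = copies)
}

# Linear predictor of the disease liability on the logit scale.
disease_logit <- function(G, effects, mhc = NULL, mhc_copies = NULL,
                          mhc_class = NULL, covars = NULL) {
  eta <- rep(effects$intercept, nrow(G))
  if (length(effects$additive)) {
    missing_ids <- setdiff(names(effects$additive), colnames(G))
    if (length(missing_ids))
      stop_named("additive effects reference unknown variants: %s",
                 paste(missing_ids, collapse = ", "))
    eta <- eta + as.vector(G[, names(effects$additive), drop = FALSE] %*%
                             effects$additive)
  }
  if (!is.null(effects$interactions) && nrow(effects$interactions)) {
    for (r in seq_len(nrow(effects$interactions))) {
      a <- G[, effects$interactions$id_a[r]]
      b <- G[, effects$interactions$id_b[r]]
      term <- if (effects$encoding == "dosage") a * b else (a >= 1) * (b >= 1)
      eta <- eta + effects$interactions$log_or[r] * term
    }
  }
  if (!is.null(mhc)) {
    stopifnot(!is.null(mhc_copies), !is.null(mhc_class))
    for (h in names(mhc$log_or))
      eta <- eta + mhc$log_or[[h]] * mhc_copies[, h]
    eta <- eta + mhc$het_bonus * (mhc_class == "DR3/DR4")
  }
  if (length(effects$covariate_betas)) {
    stopifnot(!is.null(covars),
              all(names(effects$covariate_betas) %in% colnames(covars)))
    eta <- eta + as.vector(as.matrix(covars[, names(effects$covariate_betas),
                                            drop = FALSE]) %*%
                             effects$covariate_betas)
  }
  eta
}

#' Simulate binary disease labels from a logistic model
#'
#' `P(case | x) = expit(intercept + additive + interactions + MHC terms +
#' covariate terms)`. The DR3/DR4 heterozygote bonus applies only to
#' individuals whose diplotype class is `"DR3/DR4"`.
#'
#' @param G Dosage matrix.
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @param mhc Optional [mhc_spec()]; requires `mhc_assign`.
#' @param mhc_assign Result of [assign_mhc()] (for copies and class).
#' @param covars Optional data frame of covariates.
#' @return Integer vector of case (1) / control (0) labels.
#' @export
simulate_phenotypes <- function(G, effects, seed = 1L, mhc = NULL,
                                mhc_assign = NULL, covars = NULL) {
  stopifnot(inherits(effects, "effect_spec"))
  eta <- disease_logit(G, effects, mhc = mhc,
                       mhc_copies = mhc_assign$copies,
                       mhc_class = mhc_assign$class, covars = covars)
  set.seed(seed)
  rbinom(nrow(G), 1L, expit(eta))
}

#' Simulate per-subtype ages of onset and complication indicators
#'
#' Onset is drawn from the subtype's normal distribution truncated at zero;
#' complications are Bernoulli with the subtype's odds multiplier applied to
#' the baseline probability on the odds scale.
#'
#' @param subtype Character vector of planted subtypes (cases).
#' @param spec A [clinical_spec()].
#' @param seed Integer seed.
#' @return Data frame with `onset_age` and one 0/1 column per complication.
#' @export
simulate_clinical <- function(subtype, spec, seed = 1L) {
  stopifnot(inherits(spec, "clinical_spec"))
  unknown <- setdiff(unique(subtype), spec$onset$subtype)
  if (length(unknown))
    stop_named("subtypes without clinical spec: %s", paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- length(subtype)
  i <- match(subtype, spec$onset$subtype)
  loc <- spec$onset$location[i]; sc <- spec$onset$scale[i]
  # inverse-CDF sampling from N(loc, sc) truncated to [0, Inf)
  lo <- pnorm(-loc / sc)
  onset <- loc + sc * qnorm(runif(n, lo, 1))
  out <- data.frame(onset_age = onset)
  for (cmp in names(spec$base_prob)) {
    mult <- spec$odds_multiplier[subtype, cmp]
    p <- plogis(qlogis(spec$base_prob[[cmp]]) + log(mult))
    out[[cmp]] <- rbinom(n, 1L, p)
  }
  out
}

#' Simulate a complete case-control cohort
#'
#' One call produces genotypes with block LD, the MHC-analog diplotypes,
#' covariates (sex, four genotype PCs with small planted cohort offsets,
#' cohort indicator), disease labels from the planted logistic model,
#' planted genetic subtypes among cases, clinical outcomes, and a truth
#' record sufficient to regenerate the cohort from its seed.
#'
#' @param n Number of individuals.
#' @param panel Variant panel.
#' @param effects An [effect_spec()].
#' @param mhc Optional [mhc_spec()].
#' @param clinical Optional [clinical_spec()].
#' @param subtype_prop Named numeric vector of planted subtype proportions
#'   among cases (default one subtype `s1`).
#' @param ld_rho Within-block latent correlation(s).
#' @param n_cohorts Number of sub-cohorts.
#' @param seed Master seed; stage seeds are derived with [child_seed()].
#' @return An object of class `cohort_data`: list with `dosage`, `panel`,
#'   `samples` (data frame), `mhc_class`, `haplotypes`, `truth`.
#' @export
simulate_cohort <- function(n, panel, effects, mhc = NULL, clinical = NULL,
                            subtype_prop = c(s1 = 1), ld_rho = 0,
                            n_cohorts = 2L, seed = 1L) {
  G <- simulate_genotypes(panel, n, ld_rho, seed = child_seed(seed, "genotypes"))
  mhc_assign <- NULL
  if (!is.null(mhc)) {
    mhc_assign <- assign_mhc(G, mhc, seed = child_seed(seed, "mhc"))
    G <- mhc_assign$G
  }
  set.seed(child_seed(seed, "covariates"))
  cohort_id <- sample.int(n_cohorts, n, replace = TRUE)
  covars <- data.frame(sex = rbinom(n, 1L, 0.5))
  for (k in 1:4)
    covars[[paste0("PC", k)]] <- rnorm(n) + 0.1 * (cohort_id - 1)
  covars$cohort <- cohort_id
  y <- simulate_phenotypes(G, effects, seed = child_seed(seed, "phenotypes"),
                           mhc = mhc, mhc_assign = mhc_assign, covars = covars)
  if (sum(y) == 0 || sum(y) == n)
    stop_named("degenerate cohort: %d cases out of %d", sum(y), n)
  set.seed(child_seed(seed, "subtypes"))
  subtype <- rep(NA_character_, n)
  subtype[y == 1] <- sample(names(subtype_prop), sum(y), replace = TRUE,
                            prob = subtype_prop)
  samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)), covars,
                        label = y, subtype = subtype,
                        stringsAsFactors = FALSE)
  samples$onset_age <- NA_real_
  for (cmp in c("nephropathy", "neuropathy", "cvd", "retinopathy"))
    samples[[cmp]] <- NA_integer_
  if (!is.null(clinical)) {
    clin <- simulate_clinical(subtype[y == 1], clinical,
                              seed = child_seed(seed, "clinical"))
    samples$onset_age[y == 1] <- clin$onset_age
    for (cmp in setdiff(names(clin), "onset_age"))
      samples[[cmp]][y == 1] <- clin[[cmp]]
  }
  structure(list(
    dosage = G, panel = panel, samples = samples,
    mhc_class = mhc_assign$class, haplotypes = mhc_assign$haplotypes,
    mhc_copies = mhc_assign$copies,
    truth = list(seed = seed, n = n, ld_rho = ld_rho, effects = effects,
                 mhc = mhc, clinical = clinical, subtype_prop = subtype_prop,
                 subtype = subtype, encoding = effects$encoding)
  ), class = "cohort_data")
}

#' Simulate per-individual SHAP attribution archetypes
#'
#' Generates a synthetic attribution matrix with `k` planted archetypes:
#' features are split into `k` dominant groups and individuals of archetype
#' `a` receive elevated attributions on group `a` plus Gaussian noise. Used
#' to exercise the subtype-discovery machinery under known ground truth.
#'
#' @param n Individuals.
#' @param n_features Features.
#' @param k Number of archetypes.
#' @param separation Dominant-feature mean shift in units of `noise_sd`.
#' @param noise_sd Noise standard deviation.
#' @param prop Archetype proportions (recycled, normalized).
#' @param seed Integer seed.
#' @return List with `shap` (n x n_features matrix), `subtype` (integer
#'   archetype per individual) and `dominant` (list of feature indices).
#' @export
simulate_shap_archetypes <- function(n, n_features = 40, k = 4, separation = 3,
                                     noise_sd = 1, prop = rep(1, k), seed = 1L) {
  stopifnot(n_features >= k)
  set.seed(seed)
  prop <- rep_len(prop, k); prop <- prop / sum(prop)
  subtype <- sample.int(k, n, replace = TRUE, prob = prop)
  groups <- split(seq_len(n_features),
                  rep_len(seq_len(k), n_features))
  mu <- matrix(0.2, k, n_features)
  for (a in seq_len(k)) mu[a, groups[[a]]] <- separation * noise_sd
  phi <- mu[subtype, , drop = FALSE] +
    matrix(rnorm(n * n_features, sd = noise_sd), n)
  colnames(phi) <- sprintf("feat%03d", seq_len(n_features))
  list(shap = phi, subtype = subtype, dominant = groups)
}
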