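# Shared study-condition generators and small utilities used across the
# unit and acceptance tests. Each generator is a self-contained experiment
# definition: panel, planted effects, and cohort draw from one seed.

# Adjusted Rand index between two partitions.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (mx - expected)
}

# Interaction-discovery condition: one planted multiplicative (carrier)
# MHC x non-MHC interaction on a polygenic background, or the matching
# additive-only null. 24 variants (4 MHC-analog), two sub-cohorts.
interaction_condition <- function(seed, epistatic, n = 10000) {
  panel <- variant_panel(24, n_blocks = 4L, maf = 0.3, n_mhc = 4L)
  mhc <- mhc_spec(tags = list(DR3 = "var001", DR4 = "var002", X = "var003"),
                  log_or = c(DR3 = 0.3, DR4 = 0.3, X = 0), het_bonus = 0)
  set.seed(child_seed(seed, "add"))
  add <- stats::setNames(abs(stats::rnorm(20, sd = 0.2)) + 0.06,
                         sprintf("var%03d", 5:24))
  inter <- if (epistatic)
    data.frame(id_a = "var001", id_b = "var012", log_or = 0.9) else NULL
  eff <- effect_spec(additive = add, interactions = inter,
                     intercept = stats::qlogis(0.33) - sum(add) * 0.6 -
                       (if (epistatic) 0.5 else 0),
                     encoding = "carrier")
  simulate_cohort(n, panel, eff, mhc = mhc, ld_rho = 0.4,
                  seed = child_seed(seed, "cohort"))
}

# One interaction-discovery replicate: train the tree model, test all
# pairs, and report whether the planted pair tops the significant list.
interaction_replicate <- function(seed, epistatic, n = 10000,
                                  max_rows = 250) {
  co <- interaction_condition(seed, epistatic, n)
  fx <- assemble_features(co)
  gb <- train_gbdt_cv(fx$X, co$samples$label, seed = child_seed(seed, "gb"))
  it <- compute_interactions(gb, fx$X, max_rows = max_rows,
                             seed = child_seed(seed, "it"))
  sig <- interaction_significance(it, groups = fx$groups)
  n_sig <- sum(sig$q < 0.05)
  top_hit <- n_sig > 0 && sig$q[1] < 0.05 &&
    setequal(c(sig$id_a[1], sig$id_b[1]), c("var001", "var012"))
  list(n_sig = n_sig, top_hit = top_hit, table = sig)
}

# Model-ordering condition: DR3/DR4 heterozygote super-risk plus four
# planted carrier interactions on a heterogeneous polygenic background,
# or the matching additive-only generator.
epistasis_condition <- function(seed, epistatic, n = 10000) {
  panel <- variant_panel(30, n_blocks = 5L, maf = 0.3, n_mhc = 6L)
  mhc <- mhc_spec(tags = list(DR3 = "var001", DR4 = "var002", X = "var003"),
                  log_or = c(DR3 = 0.3, DR4 = 0.3, X = 0),
                  het_bonus = if (epistatic) log(16) - 0.6 else 0)
  set.seed(child_seed(seed, "add"))
  add <- stats::setNames(abs(stats::rnorm(24, sd = 0.25)) + 0.08,
                         sprintf("var%03d", 4:27))
  inter <- if (epistatic)
    data.frame(id_a = c("var001", "var002", "var004", "var006"),
               id_b = c("var012", "var020", "var022", "var025"),
               log_or = c(0.8, 0.8, 0.7, 0.7)) else NULL
  eff <- effect_spec(additive = add, interactions = inter,
                     intercept = stats::qlogis(0.33) - sum(add) * 0.6 -
                       (if (epistatic) 1 else 0.2),
                     encoding = "carrier")
  simulate_cohort(n, panel, eff, mhc = mhc, ld_rho = 0.4,
                  seed = child_seed(seed, "cohort"))
}

# Strong discriminative architecture: high-penetrance MHC-analog
# (heterozygote class odds ratio 16) plus a polygenic background.
strong_architecture <- function(seed, n = 5000) {
  panel <- variant_panel(30, n_blocks = 5L, maf = 0.3, n_mhc = 6L)
  mhc <- mhc_spec(tags = list(DR3 = "var001", DR4 = "var002", X = "var003"),
                  log_or = c(DR3 = log(3), DR4 = log(3), X = 0),
                  het_bonus = log(16 / 9))
  set.seed(child_seed(seed, "add"))
  add <- stats::setNames(abs(stats::rnorm(24, sd = 0.4)) + 0.15,
                         sprintf("var%03d", 4:27))
  eff <- effect_spec(additive = add,
                     intercept = stats::qlogis(0.25) - sum(add) * 0.6 - 0.5)
  simulate_cohort(n, panel, eff, mhc = mhc, ld_rho = 0.4,
                  seed = child_seed(seed, "cohort"))
}

# Four-archetype SHAP-space condition with matching clinical outcomes:
# archetype 1 carries a +5-year onset shift and a 1.46-fold CVD odds
# multiplier.
archetype_condition <- function(seed, n = 4000, n_val = 1000) {
  disc <- simulate_shap_archetypes(n, n_features = 40, k = 4,
                                   separation = 3,
                                   seed = child_seed(seed, "disc"))
  val <- simulate_shap_archetypes(n_val, n_features = 40, k = 4,
                                  separation = 3,
                                  seed = child_seed(seed, "val"))
  spec <- clinical_spec(
    onset = data.frame(subtype = paste0("s", 1:4),
                       location = c(15, 10, 10, 10), scale = 3),
    odds_multiplier = matrix(c(1.46, 1, 1, 1,  rep(1, 12)), 4, 4,
                             dimnames = list(paste0("s", 1:4),
                                             c("cvd", "nephropathy",
                                               "neuropathy", "retinopathy"))))
  clin <- simulate_clinical(paste0("s", disc$subtype), spec,
                            seed = child_seed(seed, "clinical"))
  list(disc = disc, val = val, clinical = clin)
}

# Majority-vote mapping from cluster labels to planted archetypes.
map_clusters <- function(labels, truth) {
  vapply(sort(unique(labels)), function(c0) {
    tab <- table(truth[labels == c0])
    as.integer(names(tab)[which.max(tab)])
  }, 0L)
}
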