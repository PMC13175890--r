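#' Variants in linkage with a lead variant
#'
#' @param lead Lead variant id.
#' @param ld Square r-squared matrix with ids as dimnames.
#' @param threshold Linkage cutoff (default 0.1); the set is all variants
#'   with `r^2 > threshold` against the lead, lead always included.
#' @return Character vector of variant ids.
#' @export
linkage_set <- function(lead, ld, threshold = 0.1) {
  if (!lead %in% rownames(ld)) stop_named("lead %s absent from LD matrix", lead)
  union(lead, colnames(ld)[ld[lead, ] > threshold])
}

#' Wakefield approximate Bayes factor (evidence for association)
#'
#' `BF = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W)))` with `V = se^2` and
#' `z = beta / se` — the reciprocal of Wakefield's null-vs-alternative ABF,
#' so larger values mean stronger evidence of association. `W` is the prior
#' variance of the log odds ratio under the alternative.
#'
#' @param beta Effect estimate (log-OR).
#' @param se Standard error (> 0).
#' @param W Prior variance (> 0); default 0.04 (prior SD 0.2 on the log-OR),
#'   a conventional binary-trait choice.
#' @param log If `TRUE`, return the log Bayes factor (numerically safer for
#'   extreme z-scores).
#' @return Bayes factor(s), vectorized over `beta`/`se`.
#' @export
wakefield_bf <- function(beta, se, W = 0.04, log = FALSE) {
  stopifnot(all(se > 0), W >= 0)
  V <- se^2
  z <- beta / se
  lbf <- 0.5 * base::log(V / (V + W)) + z^2 * W / (2 * (V + W))
  if (log) lbf else exp(lbf)
}

#' Build a credible set from per-variant Bayes factors
#'
#' PIPs are Bayes factors normalized to sum to one over the signal's
#' linkage set; the credible set is the smallest prefix of the
#' descending-PIP ordering whose cumulative mass reaches the target
#' (greedy inclusion with `>=`, i.e. the variant that crosses the
#' threshold is included). Ties break on descending PIP then variant id.
#'
#' @param variant_id Variant ids in the linkage set.
#' @param bf Bayes factors (same length); alternatively pass `log_bf`.
#' @param mass Credible level (default 0.95).
#' @param log_bf Optional log Bayes factors (overrides `bf`).
#' @return A `credible_set` data frame ordered by descending PIP:
#'   `variant_id`, `bf`, `pip`, `cum_mass`, `in_set`.
#' @export
credible_set <- function(variant_id, bf = NULL, mass = 0.95, log_bf = NULL) {
  stopifnot(length(variant_id) >= 1, mass > 0, mass < 1 || mass == 1)
  if (is.null(log_bf)) {
    stopifnot(length(bf) == length(variant_id))
    log_bf <- base::log(bf)
  }
  stopifnot(length(log_bf) == length(variant_id))
  # normalize in log space for numerical stability
  m <- max(log_bf)
  pip <- exp(log_bf - m) / sum(exp(log_bf - m))
  ord <- order(-pip, variant_id)
  pip <- pip[ord]
  out <- data.frame(variant_id = variant_id[ord],
                    bf = exp(log_bf[ord]),
                    pip = pip,
                    cum_mass = cumsum(pip),
                    stringsAsFactors = FALSE)
  cutoff <- which(out$cum_mass >= mass - 1e-12)[1]
  out$in_set <- seq_len(nrow(out)) <= cutoff
  class(out) <- c("credible_set", class(out))
  out
}

#' Empirical coverage of the credible-set construction
#'
#' Calibration harness: each replicate simulates one region with a single
#' causal variant whose log-OR is drawn from the prior `Normal(0, W)`,
#' fits per-variant marginal logistic regressions, forms the credible set
#' for the lead (smallest p) variant's linkage set, and records whether the
#' causal variant is inside. Under a matched prior the greedy construction
#' should cover at or above the nominal mass.
#'
#' @param n_reps Number of replicate regions.
#' @param n Individuals per region.
#' @param n_variants Variants per region (one LD block).
#' @param ld_rho Latent block correlation.
#' @param W Prior variance of the causal log-OR (also used in the BF).
#' @param mass Credible level.
#' @param r2_threshold Linkage cutoff for set membership.
#' @param prevalence Baseline case probability.
#' @param seed Integer seed.
#' @param w_used Prior variance used when computing Bayes factors (defaults
#'   to `W`; set differently to probe prior misspecification).
#' @return List: `coverage` (fraction), `ci` (95% binomial CI), `n_reps`,
#'   `covered` (logical per replicate), `set_sizes`.
#' @export
coverage_experiment <- function(n_reps = 1000, n = 4000, n_variants = 30,
                                ld_rho = 0.7, W = 0.04, mass = 0.95,
                                r2_threshold = 0.1, prevalence = 0.3,
                                seed = 1L, w_used = W) {
  panel <- variant_panel(n_variants, n_blocks = 1L,
                         maf = stats::runif(n_variants, 0.1, 0.5))
  covered <- logical(n_reps)
  sizes <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    rs <- child_seed(seed, paste0("coverage", r))
    set.seed(rs)
    panel$maf <- stats::runif(n_variants, 0.1, 0.5)
    G <- simulate_genotypes(panel, n, ld_rho, seed = rs + 1L)
    causal <- sample(panel$id, 1)
    b <- stats::rnorm(1, 0, sqrt(W))
    y <- stats::rbinom(n, 1, expit(qlogis(prevalence) + b * G[, causal]))
    if (sum(y) %in% c(0, n)) { covered[r] <- NA; next }
    fits <- lapply(panel$id, function(v) fast_logistic(y, G[, v]))
    betas <- vapply(fits, `[[`, 0, "beta")
    ses <- vapply(fits, `[[`, 0, "se")
    ps <- vapply(fits, `[[`, 0, "p")
    lead <- panel$id[which.min(ps)]
    ld <- stats::cor(G)^2
    ls <- linkage_set(lead, ld, r2_threshold)
    i <- match(ls, panel$id)
    cs <- credible_set(ls, log_bf = wakefield_bf(betas[i], ses[i], w_used,
                                                 log = TRUE), mass = mass)
    covered[r] <- causal %in% cs$variant_id[cs$in_set]
    sizes[r] <- sum(cs$in_set)
  }
  ok <- !is.na(covered)
  cov_hat <- mean(covered[ok])
  ci <- stats::binom.test(sum(covered[ok]), sum(ok))$conf.int
  list(coverage = cov_hat, ci = as.numeric(ci), n_reps = sum(ok),
       covered = covered[ok], set_sizes = sizes[ok])
}
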