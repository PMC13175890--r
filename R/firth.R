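#' Firth penalized logistic association test
#'
#' Maximizes the Jeffreys-prior penalized likelihood
#' `l(beta) + 0.5 * log det I(beta)` by Newton iteration with the
#' hat-diagonal-corrected score, which keeps estimates finite even under
#' complete separation. Reports the Wald test for the dosage coefficient by
#' default; a penalized likelihood-ratio p-value is available by flag.
#'
#' @param y 0/1 outcome vector (at least one case and one control).
#' @param x Predictor of interest (variant dosage or indicator).
#' @param covars Optional covariate matrix/data frame (full rank required).
#' @param p_method `"wald"` (default) or `"plrt"` (penalized LRT).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the score norm.
#' @param variant_id Label carried into the result.
#' @return An `assoc_result` list: `variant_id`, `beta`, `se`, `z`, `p`,
#'   `af`, `n`, plus the full coefficient vector.
#' @export
firth_logistic <- function(y, x, covars = NULL, p_method = c("wald", "plrt"),
                           max_iter = 100L, tol = 1e-8, variant_id = "x") {
  p_method <- match.arg(p_method)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y))
    stop_named("need at least one case and one control")
  if (stats::var(x) == 0) stop_named("zero-variance dosage for %s", variant_id)
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x))
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    if (is.null(colnames(covars)))
      colnames(covars) <- paste0("c", seq_len(ncol(covars)))
    X <- cbind(X, covars)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_named("rank-deficient design; collinear columns: %s",
               paste(drop_cols, collapse = ", "))
  }
  fit <- firth_fit(X, y, max_iter = max_iter, tol = tol)
  beta <- fit$beta[["x"]]
  se <- fit$se[["x"]]
  z <- beta / se
  p <- if (p_method == "wald") {
    2 * stats::pnorm(-abs(z))
  } else {
    X0 <- X[, colnames(X) != "x", drop = FALSE]
    fit0 <- firth_fit(X0, y, max_iter = max_iter, tol = tol)
    stat <- 2 * (fit$loglik_pen - fit0$loglik_pen)
    stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }
  structure(list(variant_id = variant_id, beta = beta, se = se, z = z,
                 p = min(max(p, .Machine$double.xmin), 1), af = mean(x) / 2,
                 n = length(y), coef = fit$beta, se_all = fit$se,
                 converged = fit$converged),
            class = "assoc_result")
}

# Core Firth Newton solver on a full design matrix.
firth_fit <- function(X, y, max_iter = 100L, tol = 1e-8) {
  k <- ncol(X)
  beta <- numeric(k)
  beta[1] <- qlogis(mean(y) * 0.98 + 0.01)
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    info <- crossprod(X, X * w)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    info <- crossprod(X, X * w)
    Vinv <- tryCatch(solve(info), error = function(e)
      stop_named("singular information matrix in Firth fit"))
    h <- rowSums((X %*% Vinv) * X) * w
    score <- drop(crossprod(X, y - pr + h * (0.5 - pr)))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    step <- drop(Vinv %*% score)
    # step-halving if the penalized likelihood does not improve
    for (half in 0:15) {
      cand <- beta + step / 2^half
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
    }
    beta <- cand
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  pr <- plogis(eta)
  w <- pmax(pr * (1 - pr), 1e-12)
  info <- crossprod(X, X * w)
  Vinv <- solve(info)
  names(beta) <- colnames(X)
  se <- sqrt(diag(Vinv)); names(se) <- colnames(X)
  list(beta = beta, se = se, vcov = Vinv, loglik_pen = ll_old,
       converged = converged, iterations = it)
}

# Plain (unpenalized) logistic score fit for one predictor + covariates;
# used where speed matters and separation is not a concern.
fast_logistic <- function(y, x, covars = NULL) {
  X <- cbind(1, x)
  if (!is.null(covars)) X <- cbind(X, as.matrix(covars))
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  vc <- tryCatch(solve(crossprod(X, X * fit$weights)),
                 error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  beta <- fit$coefficients[2]
  se <- sqrt(vc[2, 2])
  list(beta = beta, se = se, z = beta / se,
       p = 2 * stats::pnorm(-abs(beta / se)))
}
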