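#' Derive a child seed from a master seed and an operation name
#'
#' Every stochastic operation in the package draws its own seed from the
#' master seed and a short operation label, so that individual pipeline
#' stages are reproducible in isolation: re-running one stage with the same
#' master seed gives identical output regardless of what ran before it.
#'
#' @param master Integer master seed.
#' @param op Character label of the operation (e.g. `"genotypes"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master, op) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(op))
  # deterministic polynomial string hash (base 31), kept inside 31-bit range
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 31 + k) %% 2147483629
  as.integer((abs(master) %% 2147483629 * 2654435 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

# Balanced quantile-group assignment: ranks broken deterministically,
# groups of size floor(n/g) +/- 1.
ntile_int <- function(x, g) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / length(x) * g))
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
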