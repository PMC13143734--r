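#' Normalize a non-negative vector into a categorical distribution
#'
#' Divides by the sum so the result is a proper probability vector. This is
#' the carrier type for every belief distribution in the package: state
#' posteriors, typing beliefs, policy posteriors, habit priors.
#'
#' @param raw Numeric vector with non-negative entries, at least one strictly
#'   positive.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' normalize(c(9, 1))
#' @export
normalize <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 1L) {
    stop("normalize: input must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("normalize: entries must be finite and non-negative", call. = FALSE)
  }
  s <- sum(raw)
  if (s <= 0) {
    stop("normalize: degenerate distribution (all entries zero)", call. = FALSE)
  }
  raw / s
}

#' Check the categorical invariants
#'
#' @param p Numeric vector.
#' @param tol Tolerance on the sum-to-one constraint.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_categorical <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("categorical: support size must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("categorical: entries must be finite and >= 0", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop("categorical: entries must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

is_categorical <- function(p, tol = 1e-9) {
  is.numeric(p) && length(p) >= 1L && all(is.finite(p)) && all(p >= 0) &&
    abs(sum(p) - 1) <= tol
}

#' Softmax of a real vector (natural base)
#'
#' @param x Numeric vector of log-weights.
#' @return Categorical vector proportional to `exp(x)`.
#' @export
softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# xlogx with the 0*log 0 = 0 convention
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Kullback-Leibler divergence between categorical distributions (nats)
#'
#' @param p,q Categorical vectors on the same support.
#' @return `sum(p * log(p/q))` with the `0 log 0 = 0` convention.
#' @export
kl_div <- function(p, q) {
  stopifnot(length(p) == length(q))
  i <- p > 0
  if (any(q[i] <= 0)) return(Inf)
  sum(p[i] * (log(p[i]) - log(q[i])))
}

#' Shannon entropy of a categorical distribution (nats)
#'
#' @param p Categorical vector.
#' @return Entropy in nats.
#' @export
cat_entropy <- function(p) -sum(xlogx(p))
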