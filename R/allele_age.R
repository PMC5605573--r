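#' Poisson prior over the founding copy number
#'
#' When the population-scaled mutation rate is large, a mutation may plausibly
#' enter the population in several copies in its founding generation. The
#' founding copy number is then modelled as `p ~ Poisson(lambda = theta / 2)`
#' conditioned on `p >= 1`; copy counts whose (unconditioned) Poisson
#' probability falls below `epsilon` are dropped and the retained weights are
#' renormalized. As `epsilon` grows toward 1 the prior degenerates to the
#' conventional single-copy start `p = 1`.
#'
#' @param theta population-scaled mutation rate (`> 0`).
#' @param epsilon inclusion threshold in `(0, 1)`; default `1e-5`.
#' @return an object of class `start_prior`: list with `support` (copy
#'   counts), `weights` (summing to 1), `lambda`, `epsilon`.
#' @examples
#' starting_copy_prior(0.96)         # lambda = 0.48
#' starting_copy_prior(0.96, 1 - 1e-9)$support  # degenerate: 1
#' @export
starting_copy_prior <- function(theta, epsilon = 1e-5) {
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a positive scalar")
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must lie in (0, 1)")
  lambda <- theta / 2
  p_max <- 1L
  while (stats::dpois(p_max + 1L, lambda) >= epsilon) p_max <- p_max + 1L
  support <- seq_len(p_max)
  w <- stats::dpois(support, lambda)
  keep <- w >= epsilon | support == 1L  # p = 1 always retained
  support <- support[keep]
  w <- w[keep]
  structure(list(support = support, weights = w / sum(w),
                 lambda = lambda, epsilon = epsilon),
            class = "start_prior")
}

#' @export
print.start_prior <- function(x, ...) {
  cat("Founding copy-number prior: Poisson(lambda =", x$lambda,
      ") | p >= 1, epsilon =", x$epsilon, "\n")
  print(stats::setNames(round(x$weights, 6), paste0("p=", x$support)))
  invisible(x)
}

#' Eulerian coefficients of the negative-order polylogarithm
#'
#' The numerator polynomial of `Li_{-k}(z) = z * A_k(z) / (1 - z)^(k + 1)`
#' has the Eulerian numbers as coefficients; the same polynomial in `Q`
#' (applied column-wise) forms the numerator of the `k`-th raw allele-age
#' moment. Computed by the standard triangular recurrence.
#'
#' @param k moment order (positive integer).
#' @return integer-valued numeric vector of length `k`, coefficients of
#'   `A_k(z)` in increasing powers of `z`: `k = 1` gives `1`, `k = 2` gives
#'   `c(1, 1)`, `k = 3` gives `c(1, 4, 1)`.
#' @export
eulerian_coefficients <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a positive integer")
  a <- 1
  if (k > 1) for (n in 2:k) {
    m <- seq_len(n)
    prev <- c(a, 0)
    lag  <- c(0, a)
    a <- m * prev + (n - m + 1) * lag
  }
  a
}

# x-th column of Q * (sum_m a[m+1] Q^m), assembled with matrix-vector
# products only (Horner scheme); a are the Eulerian coefficients
numerator_column <- function(Q, x_idx, a) {
  e <- numeric(nrow(Q))
  e[x_idx] <- 1
  v <- a[length(a)] * e
  if (length(a) > 1) for (m in (length(a) - 1):1)
    v <- as.numeric(Q %*% v) + a[m] * e
  as.numeric(Q %*% v)
}

#' Exact moments of the allele-age distribution
#'
#' The age of an allele observed at `x` copies, having entered the population
#' at `p` copies, has distribution `f(t) = Q^t[p, x] / N[p, x]` with
#' `N = (I - Q)^{-1}`. Its raw moments reduce to matrix identities: the mean
#' is `[Q (I-Q)^{-2}]_{p,x} / N[p,x]`, the second raw moment
#' `[Q (I+Q) (I-Q)^{-3}]_{p,x} / N[p,x]`, and in general the `k`-th moment is
#' the `(p, x)` entry of the negative-order polylogarithm `Li_{-k}(Q)` over
#' the normalizer. All quantities are obtained from one sparse LU
#' factorization of `(I - Q)'` by `k + 1` triangular solves plus sparse
#' matrix-vector products on the `x`-th column - never a matrix-matrix
#' product. Age counts generations since the founding mutation; observation
#' in the founding generation contributes age 0.
#'
#' The start may be a point copy count `p` or a [starting_copy_prior()],
#' in which case the moments are integrated over the founding copy number
#' (the factorization does not depend on `p`, so this costs only one extra
#' assembly of the start vector).
#'
#' @param ts a `transient_system`.
#' @param x observed copy count (must be a transient state label).
#' @param p founding copy count, [starting_copy_prior()], or probability
#'   vector over transient states; default 1.
#' @param f optional pre-computed [transient_factorization()].
#' @param k_max highest raw moment, between 2 and 4.
#' @return an object of class `age_moments`: list with `mean`, `variance`,
#'   `sd`, `moments` (raw moments `mu1..mu_k`), `normalizer` (`N[p, x]`),
#'   and provenance (`x`, `p`, `model`, `cutoff`).
#' @examples
#' m <- wf_model(200, theta = 0.01)
#' ts <- transient_system(wf_transition_matrix(m))
#' allele_age_moments(ts, x = 10)
#' @export
allele_age_moments <- function(ts, x, p = 1, f = NULL, k_max = 2) {
  stopifnot(inherits(ts, "transient_system"))
  if (length(k_max) != 1L || k_max < 2 || k_max > 4 || k_max != round(k_max))
    stop("'k_max' must be 2, 3 or 4 (see eulerian_coefficients() for the extension path)")
  x_idx <- match(as.integer(x), ts$states)
  if (is.na(x_idx)) stop("'x' is not a transient state")
  if (is.null(f)) f <- transient_factorization(ts)
  m <- fundamental_row(f, ts, p)
  normalizer <- m[x_idx]
  if (normalizer <= 0)
    stop("state x = ", x, " is unreachable from the start state (normalizer 0)")
  mu <- numeric(k_max)
  for (k in seq_len(k_max)) {
    m <- resolvent_iterate(f, m)   # m is now the start row of (I-Q)^-(k+1)
    ax <- numerator_column(ts$Q, x_idx, eulerian_coefficients(k))
    mu[k] <- sum(m * ax) / normalizer
  }
  variance <- mu[2] - mu[1]^2
  structure(list(mean = mu[1], variance = variance,
                 sd = sqrt(max(variance, 0)),
                 moments = stats::setNames(mu, paste0("mu", seq_len(k_max))),
                 normalizer = normalizer,
                 x = x, p = p, model = ts$model, cutoff = ts$cutoff),
            class = "age_moments")
}

#' @export
print.age_moments <- function(x, ...) {
  cat("Allele age (generations): mean =", format(x$mean, digits = 8),
      ", sd =", format(x$sd, digits = 8), "\n")
  cat("  variance =", format(x$variance, digits = 8),
      ", normalizer N[p, x] =", format(x$normalizer, digits = 8), "\n")
  invisible(x)
}

#' Truncated allele-age probability distribution
#'
#' Evaluates `f(t) = Q^t[p, x] / N[p, x]` for `t = 0..t_max` by iterated
#' vector-matrix products of the start vector with `Q` (never materializing
#' `Q^t`). Feasible for small state spaces only; the truncation mass deficit
#' `1 - sum(f)` is reported and shrinks as `t_max` grows.
#'
#' @inheritParams allele_age_moments
#' @param t_max largest age evaluated.
#' @param max_states refuse state spaces larger than this (default 2001);
#'   use [allele_age_moments()] for large populations.
#' @return an object of class `age_pmf`: list with `t`, `prob`, `deficit`,
#'   `normalizer`, `x`, `p`.
#' @export
allele_age_pmf <- function(ts, x, p = 1, t_max = 1000L, f = NULL,
                           max_states = 2001L) {
  stopifnot(inherits(ts, "transient_system"))
  n <- nrow(ts$Q)
  if (n > max_states)
    stop("state space too large for full distribution (", n, " > ", max_states,
         "); use allele_age_moments() instead")
  x_idx <- match(as.integer(x), ts$states)
  if (is.na(x_idx)) stop("'x' is not a transient state")
  if (is.null(f)) f <- transient_factorization(ts)
  b <- as_start_vector(ts, p)
  normalizer <- fundamental_row(f, ts, p)[x_idx]
  if (normalizer <= 0) stop("state x is unreachable from the start state")
  Qt <- Matrix::t(ts$Q)
  probs <- numeric(t_max + 1L)
  v <- b
  probs[1L] <- v[x_idx]
  for (t in seq_len(t_max)) {
    v <- as.numeric(Qt %*% v)
    probs[t + 1L] <- v[x_idx]
  }
  probs <- probs / normalizer
  structure(list(t = 0:t_max, prob = probs, deficit = 1 - sum(probs),
                 normalizer = normalizer, x = x, p = p),
            class = "age_pmf")
}

#' @export
print.age_pmf <- function(x, ...) {
  cat("Allele-age distribution, t = 0..", max(x$t),
      "; truncation deficit =", format(x$deficit, digits = 6), "\n", sep = "")
  invisible(x)
}
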