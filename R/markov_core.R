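#' Sparse factorization of the transposed resolvent (I - Q)'
#'
#' Computes a single sparse LU factorization of `(I - Q)'` and stores its
#' triangular factors and permutations. The factorization is reused for every
#' downstream solve: the allele-age moment chain solves systems in
#' `(I - Q)'`, while absorption-vector computations solve the untransposed
#' orientation `(I - Q) x = b` through the same factors (a permuted pair of
#' triangular solves), so no second factorization is ever required and no
#' matrix-matrix product appears anywhere in the solve path.
#'
#' Every solve is residual-checked (`max |A x - b| <= 1e-8`); if the bound is
#' exceeded one step of iterative refinement is applied, and a hard error is
#' raised if the refined residual still exceeds the bound.
#'
#' @param ts a `transient_system`.
#' @return an object of class `wf_factorization`.
#' @export
transient_factorization <- function(ts) {
  stopifnot(inherits(ts, "transient_system"))
  n <- nrow(ts$Q)
  A <- Matrix::Diagonal(n) - Matrix::t(ts$Q)
  f <- tryCatch(Matrix::lu(A), error = function(e)
    stop("(I - Q)' is numerically singular: ", conditionMessage(e)))
  ex <- Matrix::expand(f)  # A = P' L U Q (permutation matrices P, Q)
  structure(list(lu = f, A = A, n = n,
                 L = ex$L, U = ex$U, P = ex$P, Qperm = ex$Q,
                 Lt = Matrix::t(ex$L), Ut = Matrix::t(ex$U),
                 Pt = Matrix::t(ex$P)),
            class = "wf_factorization")
}

#' @export
print.wf_factorization <- function(x, ...) {
  cat("Sparse LU of (I - Q)':", x$n, "x", x$n,
      ", nnz(L) + nnz(U) =", Matrix::nnzero(x$L) + Matrix::nnzero(x$U), "\n")
  invisible(x)
}

# residual-checked solve of (I - Q)' m = b; the bound scales with the
# right-hand side so iterated solves (whose RHS norms grow with each
# resolvent power) are held to the same relative accuracy as the unit e_p
solve_resolvent_t <- function(f, b, tol = 1e-8) {
  tol <- tol * max(1, max(abs(b)))
  m <- as.numeric(Matrix::solve(f$lu, b))
  r <- b - as.numeric(f$A %*% m)
  if (max(abs(r)) > tol) {
    m <- m + as.numeric(Matrix::solve(f$lu, r))
    r <- b - as.numeric(f$A %*% m)
    if (max(abs(r)) > tol)
      stop("solve of (I - Q)' failed the residual bound (", format(max(abs(r))),
           " > ", tol, ") even after refinement")
  }
  m
}

# residual-checked solve of (I - Q) y = b via the transposed factors:
# with A = (I - Q)' = P' L U Q, solving A' y = b uses
#   z = U' \ (Q b);  w = L' \ z;  y = P' w
solve_resolvent <- function(f, b, tol = 1e-8) {
  tol <- tol * max(1, max(abs(b)))
  one_pass <- function(b) {
    z <- Matrix::solve(f$Ut, as.numeric(f$Qperm %*% b))
    w <- Matrix::solve(f$Lt, z)
    as.numeric(f$Pt %*% w)
  }
  y <- one_pass(b)
  r <- b - as.numeric(Matrix::crossprod(f$A, y))
  if (max(abs(r)) > tol) {
    y <- y + one_pass(r)
    r <- b - as.numeric(Matrix::crossprod(f$A, y))
    if (max(abs(r)) > tol)
      stop("solve of (I - Q) failed the residual bound (", format(max(abs(r))),
           " > ", tol, ") even after refinement")
  }
  y
}

# normalize a start specification into a probability vector over transient
# states: a single copy count, a start_prior, or a full numeric vector
as_start_vector <- function(ts, start) {
  n <- nrow(ts$Q)
  if (inherits(start, "start_prior")) {
    b <- numeric(n)
    idx <- match(start$support, ts$states)
    if (anyNA(idx))
      stop("prior support includes copy counts outside the transient states")
    b[idx] <- start$weights
    return(b)
  }
  if (length(start) == 1L) {
    idx <- match(as.integer(start), ts$states)
    if (is.na(idx)) stop("start state ", start, " is not a transient state")
    b <- numeric(n)
    b[idx] <- 1
    return(b)
  }
  if (length(start) != n) stop("start vector has wrong length")
  if (any(start < 0) || abs(sum(start) - 1) > 1e-8)
    stop("start vector must be a probability vector over transient states")
  as.numeric(start)
}

#' Start-state row of the fundamental matrix
#'
#' Solves `(I - Q)' m = b` where `b` is the start distribution (a point mass
#' `e_p` or a prior over founding copy numbers). The result is the start-state
#' row of the fundamental matrix `N = (I - Q)^{-1}`: entry `j` is the expected
#' number of generations spent at transient state `j` before absorption, and
#' the entry at the observed state `x` is the normalizer of the allele-age
#' distribution.
#'
#' @param f a [transient_factorization()].
#' @param ts the matching `transient_system`.
#' @param start founding copy count `p`, a [starting_copy_prior()], or a
#'   probability vector over transient states.
#' @return numeric vector over transient states (all entries `>= 0` up to
#'   roundoff).
#' @export
fundamental_row <- function(f, ts, start) {
  stopifnot(inherits(f, "wf_factorization"))
  solve_resolvent_t(f, as_start_vector(ts, start))
}

#' Iterate the resolvent chain
#'
#' Given `m_k`, the start row of `(I - Q)^{-k}`, one further triangular solve
#' of `(I - Q)' m = m_k` yields the start row of `(I - Q)^{-(k+1)}`. Repeated
#' application supplies all vectors needed for higher allele-age moments while
#' reusing the single LU factorization.
#'
#' @param f a [transient_factorization()].
#' @param m_k numeric vector, the start row of `(I - Q)^{-k}`.
#' @return the start row of `(I - Q)^{-(k+1)}`.
#' @export
resolvent_iterate <- function(f, m_k) {
  stopifnot(inherits(f, "wf_factorization"))
  if (length(m_k) != f$n) stop("dimension mismatch")
  solve_resolvent_t(f, m_k)
}

#' Absorption probabilities from a start state
#'
#' Classical absorbing-chain identity `B = N R`: the probability of ending at
#' each absorbing state. Computed as the dot products of the start row of the
#' fundamental matrix with the columns of `R` - one solve, no inverse.
#'
#' @inheritParams fundamental_row
#' @param ts a `transient_system`.
#' @return named numeric vector (one entry per absorbing column of `R`,
#'   `c(extinction=, fixation=)` for Wright-Fisher systems), summing to 1.
#' @export
absorption_probabilities <- function(ts, start, f = NULL) {
  stopifnot(inherits(ts, "transient_system"))
  if (is.null(f)) f <- transient_factorization(ts)
  m1 <- fundamental_row(f, ts, start)
  pr <- as.numeric(crossprod(ts$R, m1))
  names(pr) <- if (!is.null(colnames(ts$R)) && all(colnames(ts$R) == c("ext", "fix")))
    c("extinction", "fixation") else colnames(ts$R)
  pr
}

#' Absorption times and conditional sojourn times
#'
#' Summarizes the fate of an allele trajectory started from `start`:
#' absorption probabilities, the unconditional expected absorption time, the
#' expected times conditional on extinction and on fixation, and the
#' per-state conditional sojourn vectors
#' `sojourn_ext[j] = N[p, j] * B[j, ext] / B[p, ext]` (and likewise for
#' fixation), all in generations. Uses one row-solve for `N[p, .]` and one
#' column-solve per absorbing state for `B[., a]`, all against the same LU
#' factorization.
#'
#' If an absorption probability is numerically zero the corresponding
#' conditional quantities are reported as `NA` and flagged in `undefined`
#' rather than propagating `NaN`.
#'
#' @inheritParams absorption_probabilities
#' @return an object of class `absorption_summary`: list with
#'   `prob_extinction`, `prob_fixation`, `time_unconditional`,
#'   `time_given_extinction`, `time_given_fixation`, `sojourn_given_extinction`,
#'   `sojourn_given_fixation` (vectors over transient states), `states`,
#'   `start`, `undefined`.
#' @export
absorption_summary <- function(ts, start, f = NULL) {
  stopifnot(inherits(ts, "transient_system"))
  if (ncol(ts$R) != 2L)
    stop("absorption_summary() expects a two-boundary (extinction/fixation) system")
  if (is.null(f)) f <- transient_factorization(ts)
  bvec <- as_start_vector(ts, start)
  m1 <- solve_resolvent_t(f, bvec)
  b_ext <- solve_resolvent(f, ts$R[, 1L])
  b_fix <- solve_resolvent(f, ts$R[, 2L])
  pE <- sum(bvec * b_ext)
  pF <- sum(bvec * b_fix)
  t_unc <- sum(m1)
  undefined <- character(0)
  soj <- function(bcol, p) {
    if (p <= 0) return(rep(NA_real_, length(m1)))
    m1 * bcol / p
  }
  s_ext <- soj(b_ext, pE)
  s_fix <- soj(b_fix, pF)
  if (pE <= 0) undefined <- c(undefined, "extinction")
  if (pF <= 0) undefined <- c(undefined, "fixation")
  structure(list(
    prob_extinction = pE, prob_fixation = pF,
    time_unconditional = t_unc,
    time_given_extinction = if (pE > 0) sum(s_ext) else NA_real_,
    time_given_fixation   = if (pF > 0) sum(s_fix) else NA_real_,
    sojourn_given_extinction = s_ext,
    sojourn_given_fixation = s_fix,
    states = ts$states, start = start, undefined = undefined
  ), class = "absorption_summary")
}

#' @export
print.absorption_summary <- function(x, ...) {
  cat("Absorption summary (start:",
      if (inherits(x$start, "start_prior")) "prior over p" else x$start, ")\n")
  cat(sprintf("  P(extinction) = %.6g, P(fixation) = %.6g\n",
              x$prob_extinction, x$prob_fixation))
  cat(sprintf("  E[T] = %.6g; E[T | ext] = %.6g; E[T | fix] = %.6g generations\n",
              x$time_unconditional, x$time_given_extinction,
              x$time_given_fixation))
  if (length(x$undefined))
    cat("  undefined conditional times:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Conditional sojourn-time difference against a neutral reference
#'
#' Elementwise difference (in generations) of the extinction-conditional
#' sojourn vectors of a selected and a neutral system sharing the same state
#' space and start state; positive entries mark copy-number classes where
#' selection prolongs residency among trajectories destined for extinction.
#'
#' @param ts_selected,ts_neutral two `transient_system`s of equal dimension.
#' @param start shared start specification (see [fundamental_row()]).
#' @param f_selected,f_neutral optional pre-computed factorizations.
#' @return data.frame with columns `state` (copy count), `selected`,
#'   `neutral`, `difference`.
#' @export
sojourn_difference <- function(ts_selected, ts_neutral, start,
                               f_selected = NULL, f_neutral = NULL) {
  if (nrow(ts_selected$Q) != nrow(ts_neutral$Q))
    stop("the two systems must share the same transient dimension")
  a <- absorption_summary(ts_selected, start, f_selected)
  b <- absorption_summary(ts_neutral, start, f_neutral)
  data.frame(state = ts_selected$states,
             selected = a$sojourn_given_extinction,
             neutral = b$sojourn_given_extinction,
             difference = a$sojourn_given_extinction - b$sojourn_given_extinction)
}
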