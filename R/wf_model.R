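#' Biallelic diploid Wright-Fisher model specification
#'
#' Defines a discrete Wright-Fisher population of `Ne` diploid individuals
#' segregating a wild-type and a mutant allele. Relative fitnesses follow the
#' standard convention: wild-type homozygote 1, heterozygote `1 + s*h`, mutant
#' homozygote `1 + s`. Mutation is bidirectional with per-generation
#' probabilities `u` (wild-type to mutant) and `v` (mutant to wild-type).
#' The copy-number state space is `{0, ..., 2*Ne}` with 0 (extinction) and
#' `2*Ne` (fixation) absorbing.
#'
#' When `theta` is supplied instead of `u`/`v`, symmetric mutation is assumed
#' with `u = v = theta / (4*Ne)`, the population-scaled rate being
#' `theta = 4*Ne*u`.
#'
#' @param Ne effective diploid population size (integer, >= 2).
#' @param s selection coefficient; all genotype fitnesses must stay positive,
#'   i.e. `1 + s > 0` and `1 + s*h > 0`.
#' @param h dominance coefficient (0 recessive mutant, 0.5 additive,
#'   1 dominant).
#' @param u,v per-generation mutation probabilities in `[0, 1)`. Ignored when
#'   `theta` is given.
#' @param theta optional population-scaled mutation rate `4*Ne*u`; implies
#'   symmetric mutation.
#' @return an object of class `wf_model` with elements `Ne`, `s`, `h`, `u`,
#'   `v` and `theta` (`4*Ne*u`).
#' @examples
#' wf_model(1000, theta = 0.01)
#' wf_model(1000, s = -0.0015, h = 0, theta = 0.96)
#' @export
wf_model <- function(Ne, s = 0, h = 0.5, u = 0, v = 0, theta = NULL) {
  if (length(Ne) != 1L || !is.finite(Ne) || Ne < 2 || Ne != round(Ne))
    stop("'Ne' must be a single integer >= 2")
  if (!is.null(theta)) {
    if (!is.finite(theta) || theta < 0) stop("'theta' must be >= 0")
    u <- v <- theta / (4 * Ne)
  }
  for (nm in c("s", "h", "u", "v")) {
    val <- get(nm)
    if (length(val) != 1L || !is.finite(val)) stop("'", nm, "' must be a finite scalar")
  }
  if (1 + s <= 0 || 1 + s * h <= 0)
    stop("genotype fitnesses must be positive: need 1 + s > 0 and 1 + s*h > 0")
  if (u < 0 || u >= 1 || v < 0 || v >= 1)
    stop("mutation probabilities must lie in [0, 1)")
  structure(
    list(Ne = as.integer(Ne), s = s, h = h, u = u, v = v, theta = 4 * Ne * u),
    class = "wf_model"
  )
}

#' @export
print.wf_model <- function(x, ...) {
  cat("Wright-Fisher model: Ne =", x$Ne,
      "(", 2L * x$Ne + 1L, "copy-number states )\n")
  cat(sprintf("  s = %g (2*Ne*s = %g), h = %g\n", x$s, 2 * x$Ne * x$s, x$h))
  cat(sprintf("  u = %g, v = %g (theta = 4*Ne*u = %g)\n", x$u, x$v, x$theta))
  invisible(x)
}

#' Expected post-selection, post-mutation mutant frequency
#'
#' One deterministic step of the Wright-Fisher life cycle: viability selection
#' on genotypes (random mating, Hardy-Weinberg proportions), then mutation.
#' The returned value is the success probability of the binomial sampling step
#' that produces the next generation.
#'
#' @param q current mutant allele frequency in `[0, 1]` (vectorized).
#' @param model a [wf_model()].
#' @return expected mutant frequency, same length as `q`, in `[0, 1]`.
#' @examples
#' m <- wf_model(100, s = 0.1, h = 0.5)
#' expected_mutant_freq(0.5, m)
#' @export
expected_mutant_freq <- function(q, model) {
  stopifnot(inherits(model, "wf_model"))
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("'q' must be a frequency in [0, 1]")
  s <- model$s; h <- model$h
  num  <- (1 + s) * q^2 + (1 + s * h) * q * (1 - q)
  wbar <- (1 + s) * q^2 + 2 * (1 + s * h) * q * (1 - q) + (1 - q)^2
  psel <- num / wbar
  psel * (1 - model$v) + (1 - psel) * model$u
}

#' Wright-Fisher transition matrix with absorbing boundaries
#'
#' Row `i` (for transient `1 <= i <= 2*Ne - 1`) is the
#' `Binomial(2*Ne, psi(i / (2*Ne)))` distribution over `j = 0..2*Ne`, where
#' `psi` is [expected_mutant_freq()]. Rows 0 and `2*Ne` are absorbing identity
#' rows. Entries below `cutoff` are dropped and the rows are *not*
#' renormalized, so each row sum lies in `[1 - (2*Ne + 1)*cutoff, 1]`; with
#' the default cutoff this treats entries below machine precision as exact
#' zeros and makes the matrix sparse.
#'
#' Binomial probabilities are evaluated through `stats::dbinom` (log-space
#' internally), restricted per row to a window of +/- 9 binomial standard
#' deviations around the mean (plus a fixed margin) before thresholding; for
#' `cutoff >= 1e-16` the omitted tail mass is far below the cutoff itself.
#'
#' @param model a [wf_model()].
#' @param cutoff smallest retained transition probability, in `[0, 1e-8)`.
#' @return an object of class `wf_tmatrix`: list with `P` (sparse
#'   `dgCMatrix`, `(2*Ne+1) x (2*Ne+1)`, rows/cols indexed by copy number
#'   `0..2*Ne`), `absorbing` (`c(0, 2*Ne)`), `cutoff` and `model`.
#' @examples
#' P <- wf_transition_matrix(wf_model(10), cutoff = 0)
#' Matrix::rowSums(P$P)
#' @export
wf_transition_matrix <- function(model, cutoff = 1e-12) {
  stopifnot(inherits(model, "wf_model"))
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff < 0 || cutoff >= 1e-8)
    stop("'cutoff' must lie in [0, 1e-8)")
  n <- 2L * model$Ne
  i_tr <- seq_len(n - 1L)
  psi <- expected_mutant_freq(i_tr / n, model)
  ti <- vector("list", n - 1L); tj <- ti; tx <- ti
  for (i in i_tr) {
    p <- psi[i]
    m <- n * p
    sd <- sqrt(n * p * (1 - p))
    lo <- max(0,  floor(m - 9 * sd - 12))
    hi <- min(n, ceiling(m + 9 * sd + 12))
    j <- lo:hi
    pr <- stats::dbinom(j, n, p)
    keep <- pr >= cutoff & pr > 0
    ti[[i]] <- rep.int(i, sum(keep))
    tj[[i]] <- j[keep]
    tx[[i]] <- pr[keep]
  }
  ii <- c(unlist(ti), 0L, n)
  jj <- c(unlist(tj), 0L, n)
  xx <- c(unlist(tx), 1, 1)
  P <- Matrix::sparseMatrix(i = ii + 1L, j = jj + 1L, x = xx,
                            dims = c(n + 1L, n + 1L))
  structure(list(P = P, absorbing = c(0L, n), cutoff = cutoff, model = model),
            class = "wf_tmatrix")
}

#' @export
print.wf_tmatrix <- function(x, ...) {
  n <- nrow(x$P)
  cat("Wright-Fisher transition matrix:", n, "x", n,
      "states, nnz =", Matrix::nnzero(x$P), ", cutoff =", x$cutoff, "\n")
  invisible(x)
}

#' Transient system (Q, R) of an absorbing chain
#'
#' Restricts an absorbing transition matrix to its transient states: `Q`
#' holds transient-to-transient probabilities and `R` the transient-to-
#' absorbing probabilities, columns ordered (extinction, fixation). State
#' labels are the mutant copy counts `1..2*Ne - 1`.
#'
#' @param P a `wf_tmatrix` from [wf_transition_matrix()].
#' @return an object of class `transient_system`: list with sparse `Q`,
#'   dense two-column matrix `R` (`ext`, `fix`), integer `states`, `cutoff`
#'   and `model` (the latter two `NULL` for user-supplied systems).
#' @seealso [transient_system_from_matrices()] for the generic entry point.
#' @export
transient_system <- function(P) {
  stopifnot(inherits(P, "wf_tmatrix"))
  n <- nrow(P$P)
  abs_idx <- P$absorbing + 1L
  diag_abs <- Matrix::diag(P$P)[abs_idx]
  if (any(abs(diag_abs - 1) > 0))
    stop("absorbing rows of P are not identity rows")
  tr <- setdiff(seq_len(n), abs_idx)
  Q <- P$P[tr, tr, drop = FALSE]
  R <- cbind(ext = as.numeric(P$P[tr, 1L]),
             fix = as.numeric(P$P[tr, n]))
  structure(list(Q = Q, R = R, states = tr - 1L,
                 cutoff = P$cutoff, model = P$model),
            class = "transient_system")
}

#' Assemble a transient system from user-supplied matrices
#'
#' Entry point for the general "any finite absorbing Markov chain" path: the
#' age, absorption and sojourn machinery only needs the transient submatrix
#' `Q` and (for absorption analyses) the transient-to-absorbing block `R`.
#'
#' @param Q square matrix (dense or sparse) of transient-to-transient
#'   probabilities; coerced to a sparse `dgCMatrix`.
#' @param R optional matrix of transient-to-absorbing probabilities, one
#'   column per absorbing state (at least one). If omitted, deduced as a
#'   single column `1 - rowSums(Q)`.
#' @param states optional integer labels for the transient states (defaults
#'   to `1..nrow(Q)`).
#' @param check verify that `rowSums(Q) + rowSums(R)` is 1 within `1e-8` and
#'   all entries lie in `[0, 1]` (default `TRUE`).
#' @return a `transient_system`.
#' @examples
#' ts <- transient_system_from_matrices(matrix(0.5), matrix(c(0.25, 0.25), 1))
#' @export
transient_system_from_matrices <- function(Q, R = NULL, states = NULL,
                                           check = TRUE) {
  Q <- methods::as(methods::as(Matrix::Matrix(Q, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(Q) != ncol(Q)) stop("'Q' must be square")
  if (is.null(R)) R <- cbind(abs = 1 - Matrix::rowSums(Q))
  R <- as.matrix(R)
  if (nrow(R) != nrow(Q)) stop("'Q' and 'R' must have the same number of rows")
  if (is.null(states)) states <- seq_len(nrow(Q))
  if (check) {
    if (any(Q@x < 0) || any(Q@x > 1) || any(R < -1e-12) || any(R > 1))
      stop("transition probabilities must lie in [0, 1]")
    rs <- Matrix::rowSums(Q) + rowSums(R)
    if (any(abs(rs - 1) > 1e-8))
      stop("rowSums(Q) + rowSums(R) must equal 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
  }
  structure(list(Q = Q, R = R, states = as.integer(states),
                 cutoff = NULL, model = NULL),
            class = "transient_system")
}

#' @export
print.transient_system <- function(x, ...) {
  cat("Absorbing-chain transient system:", nrow(x$Q), "transient states,",
      ncol(x$R), "absorbing, nnz(Q) =", Matrix::nnzero(x$Q), "\n")
  invisible(x)
}

#' Read / write a transient system in MatrixMarket format
#'
#' `write_transient_system()` stores `Q` (coordinate format) and `R` (array
#' or coordinate format) as two MatrixMarket files; `read_transient_system()`
#' reads them back, so externally built absorbing chains can be analysed.
#'
#' @param ts a `transient_system`.
#' @param q_file,r_file paths of the MatrixMarket files for `Q` and `R`.
#' @return `read_transient_system()` returns a `transient_system`;
#'   `write_transient_system()` returns the two paths invisibly.
#' @export
write_transient_system <- function(ts, q_file, r_file) {
  stopifnot(inherits(ts, "transient_system"))
  Matrix::writeMM(ts$Q, q_file)
  Matrix::writeMM(methods::as(Matrix::Matrix(ts$R, sparse = TRUE),
                              "CsparseMatrix"), r_file)
  invisible(c(q_file, r_file))
}

#' @rdname write_transient_system
#' @export
read_transient_system <- function(q_file, r_file) {
  Q <- Matrix::readMM(q_file)
  R <- as.matrix(Matrix::readMM(r_file))
  colnames(R) <- if (ncol(R) == 2L) c("ext", "fix") else NULL
  transient_system_from_matrices(Q, R)
}
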