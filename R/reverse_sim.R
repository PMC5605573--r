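#' Time-reversed absorbing chain for allele-age simulation
#'
#' Builds the reversed Markov chain whose forward trajectories, started at
#' the observed copy count `x`, reproduce the allele-age distribution of
#' forward trajectories founded at `p` copies. The reversed transient matrix
#' is `Q'[j, k] = Q[k, j] * N[p, k] / N[p, j]`, and the single absorbing
#' "stop" transition leaves state `p` with probability `1 / N[p, p]` (the
#' probability that the current visit to `p` is the founding one). Only the
#' `p`-row of the fundamental matrix is needed - one triangular solve.
#'
#' States with `N[p, j] = 0` (unreachable in a trajectory founded at `p`)
#' are pruned before normalization. Row sums of the reversed chain satisfy
#' `rowSums(Q') + stop = 1` up to the cutoff-induced deficit of the forward
#' matrix.
#'
#' @param ts a `transient_system`.
#' @param p founding copy count (a transient state label).
#' @param f optional pre-computed [transient_factorization()].
#' @return an object of class `reversed_chain`: list with sparse `Qprime`,
#'   `stop_prob` vector, `states` (retained copy counts), `p`, and the
#'   `p`-row `N_row` used in the construction.
#' @export
reversed_chain <- function(ts, p, f = NULL) {
  stopifnot(inherits(ts, "transient_system"))
  p_idx <- match(as.integer(p), ts$states)
  if (is.na(p_idx)) stop("'p' is not a transient state")
  if (is.null(f)) f <- transient_factorization(ts)
  ep <- numeric(nrow(ts$Q)); ep[p_idx] <- 1
  N_row <- solve_resolvent_t(f, ep)
  N_row[N_row < 0] <- 0  # clamp roundoff
  if (N_row[p_idx] <= 0) stop("N[p, p] <= 0: invalid fundamental row")
  keep <- which(N_row > 0)
  Nk <- N_row[keep]
  Qk <- ts$Q[keep, keep, drop = FALSE]
  # Q'[j, k] = Q[k, j] N[p, k] / N[p, j]
  Qprime <- Matrix::Diagonal(x = 1 / Nk) %*% Matrix::t(Qk) %*%
    Matrix::Diagonal(x = Nk)
  Qprime <- methods::as(Qprime, "CsparseMatrix")
  stop_prob <- numeric(length(keep))
  p_new <- match(p_idx, keep)
  stop_prob[p_new] <- 1 / N_row[p_idx]
  structure(list(Qprime = Qprime, stop_prob = stop_prob,
                 states = ts$states[keep], p = as.integer(p),
                 p_index = p_new, N_row = Nk),
            class = "reversed_chain")
}

#' @export
print.reversed_chain <- function(x, ...) {
  cat("Time-reversed absorbing chain:", nrow(x$Qprime), "states, anchored at p =",
      x$p, "(stop prob", format(x$stop_prob[x$p_index], digits = 6), ")\n")
  invisible(x)
}

#' Simulate allele ages on the reversed chain
#'
#' Each replicate walks the reversed chain from the observed copy count `x`
#' until it takes the stop transition out of the founding state `p`; the
#' recorded age is the number of steps taken (generations). Sampling tables
#' (per-row cumulative probabilities) are precomputed once; the replicate
#' loop runs in compiled code driven by R's RNG, so results are fully
#' reproducible from `seed`.
#'
#' Rows are renormalized over their retained transitions plus the stop
#' probability (the forward cutoff leaves a per-row deficit below
#' `(2*Ne + 1) * cutoff`, which is folded back proportionally). Replicates
#' that exceed `max_steps` are flagged and excluded from the summary
#' statistics, never silently dropped.
#'
#' @param rc a [reversed_chain()].
#' @param x observed copy count (state the walk starts from).
#' @param replicates number of replicates (`>= 1`).
#' @param seed integer seed.
#' @param max_steps per-replicate step cap (default `1e9`; ages at
#'   `theta ~ 1` reach `1e4`-`1e5` generations, so the cap only guards
#'   corrupted inputs).
#' @param breaks histogram break specification passed to `hist()`.
#' @return an object of class `sim_summary`: list with `replicates`, `seed`,
#'   `mean`, `sd`, `se`, `histogram` (breaks and counts), `max_steps_hit`,
#'   `ages` (numeric vector, `NA` where capped).
#' @export
simulate_allele_ages <- function(rc, x, replicates, seed,
                                 max_steps = 1e9, breaks = 100) {
  stopifnot(inherits(rc, "reversed_chain"))
  if (replicates < 1) stop("'replicates' must be >= 1")
  x_idx <- match(as.integer(x), rc$states)
  if (is.na(x_idx)) stop("'x' is not in the reversed state space")
  n <- nrow(rc$Qprime)
  Tm <- methods::as(rc$Qprime, "TsparseMatrix")
  i <- Tm@i                      # 0-based row
  j <- Tm@j                      # 0-based target
  v <- Tm@x
  # append the stop outcome (target -1) on the founding state's row
  i <- c(i, rc$p_index - 1L)
  j <- c(j, -1L)
  v <- c(v, rc$stop_prob[rc$p_index])
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; v <- v[ord]
  row_ptr <- c(0L, cumsum(tabulate(i + 1L, nbins = n)))
  if (any(diff(row_ptr) == 0L)) stop("reversed chain has an empty row")
  cum <- stats::ave(v, i, FUN = cumsum)
  tot <- cum[row_ptr[-1L]]       # last cumulative entry of each row
  cum <- cum / tot[i + 1L]       # per-row renormalization (deficit ~ cutoff)
  set.seed(seed)
  res <- simulate_ages_cpp(as.integer(row_ptr), as.integer(j), cum,
                           x_idx - 1L, as.integer(replicates),
                           as.numeric(max_steps))
  ages <- res$ages
  ok <- ages[!is.na(ages)]
  hst <- if (length(ok)) {
    h <- graphics::hist(ok, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  } else list(breaks = numeric(0), counts = integer(0))
  structure(list(replicates = as.integer(replicates), seed = seed,
                 mean = if (length(ok)) mean(ok) else NA_real_,
                 sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
                 se = if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok)) else NA_real_,
                 histogram = hst,
                 max_steps_hit = res$capped, ages = ages),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat("Simulated allele ages:", x$replicates, "replicates (seed", x$seed, ")\n")
  cat(sprintf("  mean = %.4f, sd = %.4f, se = %.4f generations\n",
              x$mean, x$sd, x$se))
  if (x$max_steps_hit > 0)
    cat("  ", x$max_steps_hit, "replicates hit max_steps and were flagged\n")
  invisible(x)
}
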