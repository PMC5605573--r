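# Dense-matrix oracles for small chains: everything here goes through
# base::solve on dense matrices, independent of the sparse LU path it checks.

dense_Q <- function(ts) as.matrix(ts$Q)

dense_fundamental <- function(ts) solve(diag(nrow(ts$Q)) - dense_Q(ts))

# raw allele-age moments by brute-force summation of t^k * Q^t[p, x]
# (dense matrix powers), truncated adaptively until the tail mass deficit
# of the age distribution drops below `tol`
dense_age_moments_oracle <- function(ts, p, x, k_max = 2, tol = 1e-10,
                                     t_chunk = 2000L, t_cap = 2e5L) {
  Q <- dense_Q(ts)
  p_idx <- match(p, ts$states); x_idx <- match(x, ts$states)
  norm <- dense_fundamental(ts)[p_idx, x_idx]
  v <- numeric(nrow(Q)); v[p_idx] <- 1
  sums <- numeric(k_max)
  mass <- v[x_idx]
  t <- 0L
  repeat {
    chunk_top <- 0
    for (i in seq_len(t_chunk)) {
      v <- drop(v %*% Q)
      t <- t + 1L
      ft <- v[x_idx]
      mass <- mass + ft
      contrib <- ft * t^seq_len(k_max)
      sums <- sums + contrib
      chunk_top <- chunk_top + contrib[k_max]
    }
    done <- (1 - mass / norm < tol) &&
      (chunk_top < 1e-10 * max(sums[k_max], .Machine$double.xmin))
    if (done || t >= t_cap) break
  }
  sums / norm
}

# small fuzz grid of model specifications (Ne <= 20), fixed once
fuzz_specs <- list(
  list(Ne = 5,  s =  0.00, h = 0.5, u = 0,     v = 0),
  list(Ne = 5,  s = -0.02, h = 0.0, u = 1e-4,  v = 1e-4),
  list(Ne = 8,  s =  0.05, h = 1.0, u = 1e-3,  v = 5e-4),
  list(Ne = 12, s = -0.10, h = 0.3, u = 2e-3,  v = 2e-3),
  list(Ne = 20, s =  0.08, h = 0.0, u = 0,     v = 1e-3),
  list(Ne = 20, s =  0.00, h = 0.5, u = 5e-3,  v = 5e-3)
)

fuzz_system <- function(spec, cutoff = 0) {
  m <- wf_model(spec$Ne, s = spec$s, h = spec$h, u = spec$u, v = spec$v)
  transient_system(wf_transition_matrix(m, cutoff = cutoff))
}

# scalar geometric chain: Q = 0.5, two absorbing exits
geometric_system <- function(q = 0.5) {
  transient_system_from_matrices(matrix(q), matrix(c((1 - q) / 2, (1 - q) / 2), 1),
                                 states = 1L)
}
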