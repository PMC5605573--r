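test_that("scalar geometric chain has closed-form resolvent and times", {
  ts <- geometric_system(0.5)
  f <- transient_factorization(ts)
  m1 <- fundamental_row(f, ts, 1)
  expect_equal(m1, 2, tolerance = 1e-12)
  m2 <- resolvent_iterate(f, m1)
  m3 <- resolvent_iterate(f, m2)
  expect_equal(c(m2, m3), c(4, 8), tolerance = 1e-12)

  pr <- absorption_probabilities(ts, 1, f)
  expect_equal(unname(pr), c(0.5, 0.5), tolerance = 1e-12)
  ab <- absorption_summary(ts, 1, f)
  expect_equal(ab$time_unconditional, 2, tolerance = 1e-12)
  expect_equal(ab$time_given_extinction, 2, tolerance = 1e-12)
  expect_equal(ab$time_given_fixation, 2, tolerance = 1e-12)
})

test_that("solve-based quantities match the dense-inverse oracle", {
  for (spec in fuzz_specs) {
    ts <- fuzz_system(spec)
    f <- transient_factorization(ts)
    N <- dense_fundamental(ts)
    n <- nrow(N)
    p_idx <- 1L

    m1 <- fundamental_row(f, ts, ts$states[p_idx])
    expect_equal(m1, N[p_idx, ], tolerance = 1e-10, ignore_attr = TRUE)
    m2 <- resolvent_iterate(f, m1)
    expect_equal(m2, (N %*% N)[p_idx, ], tolerance = 1e-9, ignore_attr = TRUE)
    # ((I-Q)^2)' m2 = e_p
    A2 <- t((diag(n) - dense_Q(ts)) %*% (diag(n) - dense_Q(ts)))
    ep <- replace(numeric(n), p_idx, 1)
    expect_lt(max(abs(A2 %*% m2 - ep)), 1e-8)

    # visits sum to the unconditional absorption time
    expect_equal(sum(m1), sum(N[p_idx, ]), tolerance = 1e-10)

    B <- N %*% ts$R
    pr <- absorption_probabilities(ts, ts$states[p_idx], f)
    expect_equal(unname(pr), B[p_idx, ], tolerance = 1e-9, ignore_attr = TRUE)

    ab <- absorption_summary(ts, ts$states[p_idx], f)
    soj_ext <- N[p_idx, ] * B[, 1] / B[p_idx, 1]
    expect_equal(ab$sojourn_given_extinction, soj_ext, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(ab$time_given_extinction, sum(soj_ext), tolerance = 1e-9)
    # law of total expectation across fates
    mix <- ab$prob_extinction * ab$time_given_extinction +
      ab$prob_fixation * ab$time_given_fixation
    expect_equal(ab$time_unconditional, mix, tolerance = 1e-6)
  }
})

test_that("fundamental row equals the truncated power sum and grows monotonically", {
  ts <- fuzz_system(fuzz_specs[[1]])  # Ne = 5 neutral drift
  f <- transient_factorization(ts)
  m1 <- fundamental_row(f, ts, 1)
  Q <- dense_Q(ts)
  v <- replace(numeric(nrow(Q)), 1, 1)
  acc <- v
  partial_at_x <- numeric(0)
  for (t in 1:10000) {
    v <- drop(v %*% Q)
    acc <- acc + v
    if (t <= 50) partial_at_x <- c(partial_at_x, acc[3])
  }
  expect_equal(acc, m1, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(partial_at_x) >= 0))
  expect_true(all(partial_at_x <= m1[3] + 1e-12))
})

test_that("neutral drift fixes with probability p / (2 Ne)", {
  ts <- transient_system(wf_transition_matrix(wf_model(30), cutoff = 0))
  f <- transient_factorization(ts)
  for (p in c(1, 7, 30, 55)) {
    pr <- absorption_probabilities(ts, p, f)
    expect_equal(unname(pr["fixation"]), p / 60, tolerance = 1e-6)
  }
})

test_that("solves satisfy the residual bound on a large sparse system", {
  m <- wf_model(1000, s = -3 / 2000, h = 0, theta = 0.96)
  ts <- transient_system(wf_transition_matrix(m))
  f <- transient_factorization(ts)
  n <- nrow(ts$Q)
  ep <- replace(numeric(n), 1, 1)
  m1 <- fundamental_row(f, ts, 1)
  A <- Matrix::Diagonal(n) - Matrix::t(ts$Q)
  expect_lt(max(abs(as.numeric(A %*% m1) - ep)), 1e-8)
  # untransposed orientation, used for absorption vectors
  b <- wfage:::solve_resolvent(f, ts$R[, 1])
  expect_lt(max(abs(as.numeric(Matrix::crossprod(A, b)) - ts$R[, 1])), 1e-8)
})

test_that("sojourn differences vanish for identical models and match the oracle", {
  ts_n <- fuzz_system(fuzz_specs[[1]])
  d0 <- sojourn_difference(ts_n, ts_n, 3)
  expect_equal(d0$difference, rep(0, nrow(d0)), tolerance = 1e-10)

  spec <- list(Ne = 5, s = -0.05, h = 0, u = 0, v = 0)
  ts_s <- fuzz_system(spec)
  d <- sojourn_difference(ts_s, ts_n, 3)
  N_s <- dense_fundamental(ts_s); N_n <- dense_fundamental(ts_n)
  B_s <- N_s %*% ts_s$R; B_n <- N_n %*% ts_n$R
  oracle <- N_s[3, ] * B_s[, 1] / B_s[3, 1] - N_n[3, ] * B_n[, 1] / B_n[3, 1]
  expect_equal(d$difference, oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a vanishing absorption probability is flagged, not propagated as NaN", {
  ts <- transient_system_from_matrices(matrix(0.5), matrix(c(0.5, 0), 1))
  ab <- absorption_summary(ts, 1)
  expect_equal(ab$prob_extinction, 1, tolerance = 1e-12)
  expect_true(is.na(ab$time_given_fixation))
  expect_identical(ab$undefined, "fixation")
  expect_false(anyNA(ab$sojourn_given_extinction))
})
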