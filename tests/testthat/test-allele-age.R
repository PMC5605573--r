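test_that("geometric chain age distribution is exact to closed form", {
  ts <- geometric_system(0.5)
  f <- transient_factorization(ts)
  am <- allele_age_moments(ts, x = 1, p = 1, f = f)
  expect_equal(am$mean, 1, tolerance = 1e-12)        # q / (1 - q)
  expect_equal(am$variance, 2, tolerance = 1e-12)    # q / (1 - q)^2
  expect_equal(am$normalizer, 2, tolerance = 1e-12)

  pmf <- allele_age_pmf(ts, x = 1, p = 1, t_max = 40, f = f)
  expect_equal(pmf$prob, 0.5^(1 + pmf$t), tolerance = 1e-12)
  expect_true(all(diff(cumsum(pmf$prob)) >= 0))
  expect_true(all(cumsum(pmf$prob) <= 1 + 1e-12))
  # deficit shrinks as the truncation horizon grows
  d10 <- allele_age_pmf(ts, 1, 1, t_max = 10, f = f)$deficit
  expect_gt(d10, pmf$deficit)
})

test_that("moments from the solve chain match brute-force pmf summation", {
  # hand-checked case: weak selection against a recessive with faint mutation
  ts <- fuzz_system(list(Ne = 5, s = -0.02, h = 0, u = 1e-4, v = 1e-4))
  oracle <- dense_age_moments_oracle(ts, p = 1, x = 3, k_max = 2)
  am <- allele_age_moments(ts, x = 3, p = 1)
  expect_equal(am$mean, oracle[1], tolerance = 1e-6)
  expect_equal(am$moments[["mu2"]], oracle[2], tolerance = 1e-6)

  # fuzz grid, including third and fourth moments
  for (spec in fuzz_specs[c(1, 3, 4)]) {
    ts <- fuzz_system(spec)
    x <- min(3, spec$Ne)
    oracle <- dense_age_moments_oracle(ts, p = 1, x = x, k_max = 4)
    am <- allele_age_moments(ts, x = x, p = 1, k_max = 4)
    expect_equal(unname(am$moments), oracle, tolerance = 1e-6)
  }
})

test_that("full distribution integrates to its own moments", {
  for (spec in fuzz_specs[c(2, 6)]) {
    ts <- fuzz_system(spec)
    f <- transient_factorization(ts)
    x <- 3
    am <- allele_age_moments(ts, x = x, p = 1, f = f)
    t_max <- 2000L
    repeat {
      pmf <- allele_age_pmf(ts, x = x, p = 1, t_max = t_max, f = f)
      if (pmf$deficit < 1e-10 || t_max > 2e5) break
      t_max <- t_max * 4L
    }
    expect_equal(sum(pmf$t * pmf$prob), am$mean, tolerance = 1e-6)
    expect_equal(sum(pmf$t^2 * pmf$prob), am$moments[["mu2"]], tolerance = 1e-6)
  }
})

test_that("Eulerian coefficients follow the polylogarithm expansion", {
  expect_equal(eulerian_coefficients(1), 1)
  expect_equal(eulerian_coefficients(2), c(1, 1))
  expect_equal(eulerian_coefficients(3), c(1, 4, 1))
  expect_equal(eulerian_coefficients(4), c(1, 11, 11, 1))
  expect_error(eulerian_coefficients(0), "positive")
  # Li_{-4}(z) = z A_4(z) / (1 - z)^5 against direct series summation
  z <- 0.3
  a <- eulerian_coefficients(4)
  closed <- z * sum(a * z^(0:3)) / (1 - z)^5
  series <- sum((1:200)^4 * z^(1:200))
  expect_equal(closed, series, tolerance = 1e-12)
})

test_that("founding copy-number prior truncates and renormalizes a Poisson", {
  pr <- starting_copy_prior(0.96)
  expect_equal(pr$lambda, 0.48)
  # support by direct pmf evaluation
  p_max <- max(which(dpois(1:50, 0.48) >= 1e-5))
  expect_equal(pr$support, seq_len(p_max))
  expect_equal(sum(pr$weights), 1, tolerance = 1e-14)
  expect_equal(pr$weights, dpois(pr$support, 0.48) / sum(dpois(pr$support, 0.48)),
               tolerance = 1e-14)
  expect_error(starting_copy_prior(0), "positive")
  expect_error(starting_copy_prior(0.96, 2), "epsilon")
})

test_that("a degenerate prior reproduces the single-copy start exactly", {
  ts <- fuzz_system(fuzz_specs[[6]])
  f <- transient_factorization(ts)
  pr <- starting_copy_prior(0.2, epsilon = 1 - 1e-12)
  expect_identical(pr$support, 1L)
  a_prior <- allele_age_moments(ts, x = 3, p = pr, f = f)
  a_point <- allele_age_moments(ts, x = 3, p = 1, f = f)
  expect_identical(a_prior$mean, a_point$mean)
  expect_identical(a_prior$variance, a_point$variance)
})

test_that("integrating over p barely moves the mean when mutation is weak", {
  m <- wf_model(1000, theta = 0.1)
  ts <- transient_system(wf_transition_matrix(m))
  f <- transient_factorization(ts)
  a1 <- allele_age_moments(ts, x = 10, p = 1, f = f)
  ap <- allele_age_moments(ts, x = 10, p = starting_copy_prior(0.1), f = f)
  expect_lt(abs(ap$mean - a1$mean) / a1$mean, 1e-3)
})

test_that("allele age is nearly symmetric in the sign of additive selection", {
  Ne <- 1000
  mean_at <- function(tns) {
    m <- wf_model(Ne, s = tns / (2 * Ne), h = 0.5)
    allele_age_moments(transient_system(wf_transition_matrix(m)), x = 10)$mean
  }
  mu0 <- mean_at(0)
  expect_lt(abs(mean_at(3) - mean_at(-3)) / mu0, 0.05)
})

test_that("degenerate inputs are refused with guidance", {
  # x unreachable from p: two non-communicating states
  ts <- transient_system_from_matrices(diag(c(0.5, 0.5)),
                                       cbind(c(0.25, 0.25), c(0.25, 0.25)))
  expect_error(allele_age_moments(ts, x = 2, p = 1), "unreachable")
  # full-distribution guard for large state spaces
  big <- fuzz_system(fuzz_specs[[5]])
  expect_error(allele_age_pmf(big, x = 3, max_states = 10), "too large")
  expect_error(allele_age_moments(fuzz_system(fuzz_specs[[1]]), x = 3, k_max = 5),
               "k_max")
})
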