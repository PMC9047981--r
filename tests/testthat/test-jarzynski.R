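test_that("the estimator reduces to its closed forms", {
  # degenerate ensemble: every work equal
  expect_equal(jarzynski_estimate(rep(3.7, 25), 298), 3.7)

  # two-term ensemble {0, 100}: direct evaluation of the exponential mean
  b <- 1 / kBT(298)
  ref <- -(1 / b) * log(0.5 * (1 + exp(-100 * b)))
  expect_equal(jarzynski_estimate(c(0, 100), 298), ref, tolerance = 1e-6)

  # extreme works must not overflow thanks to the max shift
  expect_true(is.finite(jarzynski_estimate(c(1000, 2000), 298)))
  expect_error(jarzynski_estimate(numeric(0), 298), "estimation error")
})

test_that("Gaussian work ensembles recover mu - beta sigma^2 / 2", {
  set.seed(11)
  mu <- 2; s <- 0.5; n <- 1e5
  w <- rnorm(n, mu, s)
  b <- 1 / kBT(298)
  est <- jarzynski_estimate(w, 298)
  ref <- mu - b * s^2 / 2
  # Monte-Carlo SE of the estimator by the delta method
  ew <- exp(-b * (w - mean(w)))
  se <- sd(ew) / (b * mean(ew) * sqrt(n))
  expect_lt(abs(est - ref), 3 * se)
})

test_that("second law and invariances hold on random ensembles", {
  set.seed(5)
  for (rep in 1:20) {
    w <- rnorm(30, runif(1, -5, 5), runif(1, 0.01, 2))
    est <- jarzynski_estimate(w, 298)
    expect_lte(est, mean(w))
    # permutation invariance
    expect_equal(jarzynski_estimate(sample(w), 298), est)
    # shifting all works by c shifts the estimate by exactly c
    expect_equal(jarzynski_estimate(w + 1.3, 298), est + 1.3,
                 tolerance = 1e-10)
  }
  # equality iff zero variance
  expect_equal(jarzynski_estimate(rep(1, 10), 298), 1)
})

test_that("bootstrap errors are deterministic and calibrated", {
  expect_equal(bootstrap_error(rep(2, 50), 298, seed = 3), 0)
  set.seed(6)
  w0 <- rnorm(40, 1, 0.5)
  b1 <- bootstrap_error(w0, 298, seed = 8)
  # fixed seed, repeated call: identical, whatever the ambient RNG state
  set.seed(1234)
  expect_identical(bootstrap_error(w0, 298, seed = 8), b1)
  expect_warning(e <- bootstrap_error(1, 298), "fewer than 2")
  expect_identical(e, Inf)

  # near-linear regime: agrees with the delta-method closed form
  set.seed(21)
  w <- rnorm(2000, 1, 0.3)
  b <- 1 / kBT(298)
  ew <- exp(-b * (w - mean(w)))
  se_delta <- sd(ew) / (b * mean(ew) * sqrt(length(w)))
  se_boot <- bootstrap_error(w, 298, n_boot = 1000, seed = 2)
  expect_lt(abs(se_boot - se_delta) / se_delta, 0.2)
})

test_that("profiles follow the traces and locate their minimum", {
  lam <- seq(5, 3, by = -0.5)
  tr1 <- work_trace(time = 0:4, lambda = lam, work = c(0, 1, 0.5, -1, 2))
  # single trace: the profile is the trace itself
  p1 <- build_profile(list(tr1), 298)
  expect_equal(p1$dF, tr1$work_kcal_mol)
  expect_equal(p1$err[1], 0)

  # permuting trajectory ids leaves the profile unchanged
  tr2 <- work_trace(0:4, lam, c(0, 0.5, 1, -0.5, 1.5), id = 2)
  pa <- build_profile(list(tr1, tr2), 298, seed = 5)
  pb <- build_profile(list(tr2, tr1), 298, seed = 5)
  expect_equal(pa$dF, pb$dF)

  # mismatched grids are an alignment error
  tr3 <- work_trace(0:3, lam[1:4], c(0, 1, 2, 3), id = 3)
  expect_error(build_profile(list(tr1, tr3), 298), "alignment")

  # V-shaped interior minimum
  mn <- profile_minimum(p1)
  expect_equal(mn$lambda, 3.5)
  expect_equal(mn$dF, -1)
  # monotone decreasing profile: the endpoint
  trd <- work_trace(0:4, lam, c(0, -1, -2, -3, -4))
  expect_equal(profile_minimum(build_profile(list(trd), 298))$lambda, 3)
  # ties broken toward the schedule end
  trt <- work_trace(0:4, lam, c(0, -1, 0, -1, 0))
  expect_equal(profile_minimum(build_profile(list(trt), 298))$lambda, 3.5)
})

test_that("work traces validate their invariants", {
  expect_error(work_trace(0:1, c(1, 2), c(0.5, 1)), "start at 0")
  expect_error(work_trace(0:2, c(1, 2, 1.5), c(0, 1, 2)), "monotone")
})
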