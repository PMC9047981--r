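test_that("toy dimers are deterministic and carry eleven restraints", {
  spec <- toy_dimer_spec(beads = 3, seed = 12)
  t1 <- make_toy_dimer(spec)
  t2 <- make_toy_dimer(spec)
  expect_identical(t1$system$positions, t2$system$positions)
  expect_equal(restraint_census(t1$restraints), 11L)
  # monomer COMs sit on the X axis at the prescribed spacing
  expect_equal(unname(monomer_com(t1$system, "I")), c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(cv_com_distance_x(t1$system), 9)
  # one bead per monomer is an accepted degenerate dimer
  t3 <- make_toy_dimer(toy_dimer_spec(beads = 1))
  expect_equal(nrow(t3$system$positions), 2L)
  expect_equal(restraint_census(t3$restraints), 11L)
  expect_error(toy_dimer_spec(beads = 0), "invalid toy spec")
})

test_that("quadrature oracle reproduces closed-form free energies", {
  flat <- function(x) rep(0, length(x))
  expect_equal(exact_free_energy_1d(flat, 298, c(0, 1), c(2, 3))$dF, 0,
               tolerance = 1e-10)

  # harmonic well vs flat window: Gaussian partition ratio
  kk <- 20; L <- 2
  harm <- function(x) 0.5 * kk * x^2
  pot <- list(bound = harm, unbound = flat)
  res <- exact_free_energy_1d(pot, 298, bound_window = c(-6, 6),
                              unbound_window = c(0, L))
  ref <- -kBT(298) * log(sqrt(2 * pi * kBT(298) / kk) / L)
  expect_equal(res$dF, ref, tolerance = 1e-8)
  expect_lt(res$error, 1e-8)

  # square well of depth eps in the cold limit: dF -> -eps
  eps <- 5
  sq <- function(x) ifelse(x < 1, -eps, 0)
  res2 <- exact_free_energy_1d(sq, temperature = 30,
                               bound_window = c(0, 1),
                               unbound_window = c(1, 2))
  expect_equal(res2$dF, -eps, tolerance = 1e-6)

  # 1-D standard-state term: referencing the unbound state to a standard
  # length adds +kBT log(L0 / L_u); for flat windows of lengths 1 and 0.5
  # the referenced result is exactly 0
  res_raw <- exact_free_energy_1d(flat, 298, c(0, 1), c(2, 2.5))
  expect_equal(res_raw$dF, -kBT(298) * log(2), tolerance = 1e-10)
  res3 <- exact_free_energy_1d(flat, 298, c(0, 1), c(2, 2.5),
                               standard_volume = 1)
  expect_equal(res3$dF, res_raw$dF + kBT(298) * log(1 / 0.5),
               tolerance = 1e-10)
  expect_equal(res3$dF, 0, tolerance = 1e-10)
})

test_that("harmonic release reference follows (n/2) kBT log(k2/k1)", {
  expect_equal(harmonic_release_reference(50, 50), 0)
  v <- harmonic_release_reference(50, 0.5, n_dof = 1, temperature = 298)
  expect_equal(v, 0.5 * kBT(298) * log(0.01))
  expect_equal(v, -1.364, tolerance = 1e-3)
  expect_equal(harmonic_release_reference(50, 0.5, n_dof = 2), 2 * v)
  expect_error(harmonic_release_reference(50, 0), "domain error")
})

test_that("structure fixtures plant their geometry exactly", {
  # pi-pi: planted distance/angle recovered by the detector
  fx <- make_structure_fixture("pipi", distance = 4, angle = 0)
  r <- detect_pipi(fx)
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "pi-pi-parallel")
  # hbond: planted O-N distance and angle
  hb <- detect_hbonds(make_structure_fixture("hbond", on_distance = 2.8,
                                             dha_angle = 160))
  expect_equal(nrow(hb), 1L)
  # multiframe occupancy parameter is honoured
  mf <- make_structure_fixture("multiframe", occupancy = 0.7, n_frames = 10)
  expect_equal(n_frames(mf), 10L)
  expect_error(make_structure_fixture("pipi", distance = -1), "domain error")
})

test_that("fixtures round-trip through PDB text to 1e-3 A", {
  for (kind in c("pipi", "hbond")) {
    fx <- make_structure_fixture(kind)
    back <- read_pdb(write_pdb(fx))
    expect_equal(back$frames[[1]], fx$frames[[1]], tolerance = 1.1e-3)
    expect_identical(back$atoms$name, fx$atoms$name)
  }
  mf <- make_structure_fixture("multiframe", n_frames = 4)
  back <- read_pdb(write_pdb(mf))
  expect_equal(n_frames(back), 4L)
  for (f in 1:4)
    expect_equal(back$frames[[f]], mf$frames[[f]], tolerance = 1.1e-3)
})

test_that("toy trajectories export as analyzable multi-model PDB", {
  toy <- make_toy_dimer(toy_dimer_spec(beads = 2, seed = 5), separation = 7)
  eq <- run_equilibrium(toy$system, toy$restraints, dt = 0.002,
                        n_steps = 200, seed = 3, stride = 50)
  st <- toy_frames_to_structure(eq$frames, toy$system)
  expect_gte(n_frames(st), 3L)
  back <- read_pdb(write_pdb(st))
  expect_equal(n_frames(back), n_frames(st))
  expect_equal(sort(unique(back$atoms$chain)), c("A", "B"))
})
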