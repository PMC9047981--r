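test_that("the collective variable is the mass-weighted COM X distance", {
  sys <- two_bead_system(x2 = 10)
  expect_equal(cv_com_distance_x(sys), 10)

  # mirror through the YZ plane leaves the CV unchanged
  mirrored <- sys$positions
  mirrored[, 1] <- -mirrored[, 1]
  expect_equal(cv_com_distance_x(sys, positions = mirrored), 10)

  # mass weighting: monomer I beads of mass 1 and 3 at x = 0 and 4
  sys2 <- toy_system(rbind(c(0, 0, 0), c(4, 0, 0), c(10, 0, 0)),
                     masses = c(1, 3, 2), monomer = c("I", "I", "II"),
                     epsilon = 1, sigma = 1)
  expect_equal(cv_com_distance_x(sys2), 7)
})

test_that("degenerate systems are rejected", {
  expect_error(toy_system(rbind(c(0, 0, 0)), 1, "I", 1, 1),
               "non-empty monomer")
  expect_error(toy_system(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, -1),
                          c("I", "II"), 1, 1), "positive")
})

test_that("restraint energies match their closed forms", {
  sys <- two_bead_system(x2 = 10)
  # CV spring at its centre: zero energy, zero force
  rs0 <- restraint_set(cv_k = 50, cv_center = 10)
  re0 <- restraint_energy(sys, rs0)
  expect_equal(re0$energy, 0)
  expect_equal(max(abs(re0$forces)), 0)
  # displaced by 1 A: (1/2) * 50 * 1^2 = 25
  rs1 <- restraint_set(cv_k = 50, cv_center = 9)
  expect_equal(restraint_energy(sys, rs1)$energy, 25)
})

test_that("flat-bottom umbrella is zero inside the window and C1 at knots", {
  kn <- list(k = 50, r1 = 25.5, r2 = 25.6, r3 = 26.4, r4 = 26.5)
  mk <- function(r) {
    sys <- two_bead_system(x2 = r)
    rs <- restraint_set(cv_k = 0, cv_center = r, flat_bottom = kn)
    restraint_energy(sys, rs)$energy
  }
  expect_equal(mk(26.0), 0)
  expect_equal(mk(25.6), 0)
  # continuity and matched slope at each knot
  h <- 1e-7
  for (r in unlist(kn[c("r1", "r2", "r3", "r4")])) {
    expect_lt(abs(mk(r + h) - mk(r - h)), 1e-5)
    slope_in <- (mk(r) - mk(r - h)) / h
    slope_out <- (mk(r + h) - mk(r)) / h
    expect_lt(abs(slope_in - slope_out), 1e-4)
  }
  # linear continuation beyond the outer knots: constant slope
  s1 <- (mk(25.0) - mk(24.5)) / 0.5
  s2 <- (mk(24.5) - mk(24.0)) / 0.5
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_error(restraint_set(flat_bottom = list(k = 1, r1 = 2, r2 = 1,
                                                r3 = 3, r4 = 4)),
               "knots")
})

test_that("restraint forces are exact negative gradients", {
  set.seed(99)
  toy <- make_toy_dimer(toy_dimer_spec(beads = 3, seed = 4), separation = 6)
  rs <- toy$restraints
  rs$flat_bottom <- list(k = 20, r1 = 4, r2 = 5, r3 = 7, r4 = 8)
  for (rep in 1:4) {
    x <- toy$system$positions + matrix(rnorm(18, 0, 0.25), 6, 3)
    pe <- potential_energy(toy$system, rs, positions = x)
    h <- 1e-5
    num <- matrix(0, 6, 3)
    for (i in 1:6) for (d in 1:3) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      num[i, d] <- -(potential_energy(toy$system, rs, positions = xp)$energy -
                       potential_energy(toy$system, rs, positions = xm)$energy) /
        (2 * h)
    }
    expect_lt(max(abs(num - pe$forces)) / max(abs(pe$forces)), 1e-6)
  }
})

test_that("deterministic limit conserves / dissipates energy as expected", {
  sys <- two_bead_system()
  rs <- one_dof_restraints(k = 50)
  total_energy <- function(st) {
    pe <- potential_energy(sys, rs, positions = st$positions)
    ke <- 0.5 * sum(sys$masses * rowSums(st$velocities^2)) / 418.4
    pe$energy + ke
  }
  # friction = 0, T = 0: velocity Verlet; the shadow-energy deviation is
  # bounded (no drift) and scales as O(dt^2)
  drift <- function(dt, n) {
    st <- sim_state(rbind(c(0, 0, 0.3), c(30, 0, 0)))
    e0 <- total_energy(st)
    dmax <- 0
    for (i in seq_len(n)) {
      st <- step_langevin(st, sys, rs, dt = dt, friction = 0,
                          temperature = 0)
      dmax <- max(dmax, abs(total_energy(st) - e0))
    }
    dmax
  }
  d1 <- drift(0.002, 200)
  d2 <- drift(0.001, 400)
  expect_lt(d1, 5e-3)
  expect_gt(d1 / d2, 2.5)   # quadratic in dt
  expect_lt(d1 / d2, 6)
  st <- sim_state(rbind(c(0, 0, 0.3), c(30, 0, 0)))
  e0 <- total_energy(st)

  # friction > 0, T = 0: dissipative descent, energy non-increasing
  st <- sim_state(rbind(c(0, 0, 0.3), c(30, 0, 0)))
  e_prev <- total_energy(st)
  for (i in 1:200) {
    st <- step_langevin(st, sys, rs, dt = 0.002, friction = 5,
                        temperature = 0)
    e <- total_energy(st)
    expect_lt(e, e_prev + 1e-6)
    e_prev <- e
  }
  expect_lt(e_prev, 0.5 * e0)
})

test_that("thermal equilibrium satisfies equipartition", {
  # both beads restrained in z with k = 50; var(z1 - z2) = 2 kBT / k
  sys <- two_bead_system()
  rs <- restraint_set(cv_k = 0, cv_center = 30,
                      points = data.frame(bead = 1:2, type = "zfix",
                                          k = 50, y0 = 0, z0 = 0))
  eq <- run_equilibrium(sys, rs, dt = 0.002, n_steps = 40000, seed = 17,
                        n_traj = 8, n_equil = 2000, stride = 20)
  v <- var(eq$com_sep[, 3])
  expect_equal(v, 2 * kBT(298) / 50, tolerance = 0.05)
})

test_that("identical seeds give bit-identical trajectories", {
  toy <- make_toy_dimer(toy_dimer_spec(beads = 2, seed = 3), separation = 7)
  sch <- smd_schedule("center", lambda0 = 7, v = -0.5, duration = 2)
  r1 <- run_smd(toy$system, toy$restraints, sch, dt = 0.002, seed = 123,
                n_traj = 3, n_equil = 200)
  r2 <- run_smd(toy$system, toy$restraints, sch, dt = 0.002, seed = 123,
                n_traj = 3, n_equil = 200)
  expect_identical(r1$works, r2$works)
  expect_identical(r1$traces[[2]]$work_kcal_mol, r2$traces[[2]]$work_kcal_mol)
  # trajectory streams are per-index: trajectory 1 sees the same noise
  # whatever the ensemble size (equal up to float associativity of the
  # vectorized force evaluation)
  r3 <- run_smd(toy$system, toy$restraints, sch, dt = 0.002, seed = 123,
                n_traj = 1, n_equil = 200)
  expect_equal(r3$works[1], r1$works[1], tolerance = 1e-10)

  # step_langevin under an explicit seed is reproducible too
  sys <- two_bead_system(); rs <- one_dof_restraints()
  run_one <- function() {
    set.seed(9)
    st <- sim_state(rbind(c(0, 0, 0.2), c(30, 0, 0)))
    for (i in 1:50) st <- step_langevin(st, sys, rs, dt = 0.002)
    st$positions
  }
  expect_identical(run_one(), run_one())
})

test_that("work accumulation is zero for static schedules and additive in time", {
  sys <- two_bead_system(x2 = 10)
  rs <- restraint_set(cv_k = 50, cv_center = 10)
  sch0 <- smd_schedule("center", lambda0 = 10, v = 0, duration = 1)
  out <- run_smd(sys, rs, sch0, dt = 0.002, seed = 4, n_traj = 2)
  expect_equal(max(abs(out$works)), 0)
  expect_equal(max(abs(out$traces[[1]]$work_kcal_mol)), 0)

  # contiguous segments: one 200-step pass equals 100 + 100 on the same
  # RNG stream
  rs2 <- restraint_set(cv_k = 50, cv_center = 10,
                       schedule = smd_schedule("center", 10, -1, 0.4))
  set.seed(7)
  st <- sim_state(rbind(c(0, 0, 0), c(10, 0, 0)))
  for (i in 1:200) st <- step_langevin(st, sys, rs2, dt = 0.002)
  w_once <- st$work
  set.seed(7)
  st <- sim_state(rbind(c(0, 0, 0), c(10, 0, 0)))
  for (i in 1:100) st <- step_langevin(st, sys, rs2, dt = 0.002)
  w_mid <- st$work
  for (i in 1:100) st <- step_langevin(st, sys, rs2, dt = 0.002)
  expect_identical(st$work, w_once)
  expect_lt(abs((st$work - w_mid) + w_mid - w_once), 1e-12)
})

test_that("schedule/step mismatches and blow-ups are reported", {
  sys <- two_bead_system()
  rs <- one_dof_restraints()
  sch <- smd_schedule("center", 30, -1, duration = 1)
  expect_error(run_smd(sys, rs, sch, dt = 0.002, n_steps = 123),
               "configuration error")
  st <- sim_state(rbind(c(0, 0, NaN), c(30, 0, 0)))
  expect_error(step_langevin(st, sys, rs, dt = 0.002),
               "bead 1")
})
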