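# End-to-end driver: run the three virtual processes of the restrained
# thermodynamic cycle on a toy dimer and compare the assembled binding
# free energy against the exact 1-D quadrature oracle.

#' Run the full thermodynamic cycle on a toy dimer
#'
#' Simulates the three virtual processes - release of all restraints in
#' the unbound state (A), restrained pulling from the unbound to the
#' bound separation (B, with the bound point taken at the free-energy
#' profile minimum), and release of all restraints in the bound state
#' (C) - assembles `-dF_A + dF_B + dF_C`, measures the correction
#' inputs from restrained equilibrium runs, and evaluates the exact
#' quadrature reference for the same pair of weakly-restrained end
#' states. Releases go to a small force-constant floor `k_floor`
#' rather than zero (a fully free state has no normalizable
#' reference); the oracle includes the same residual CV spring, and
#' the transverse restraint contributions cancel between processes A
#' and C by construction.
#'
#' @param spec A [toy_dimer_spec()]; the default one-bead-per-monomer
#'   toy is the configuration whose cycle is exactly closable.
#' @param unbound Unbound monomer separation (Angstrom).
#' @param bound_target End of the pulling schedule (Angstrom).
#' @param k Restrained-state force constant (kcal/mol/A^2).
#' @param k_floor Release-target force constant (kcal/mol/A^2), > 0.
#' @param v_pull Pulling speed magnitude (A/ps).
#' @param release_time Duration of each force-constant ramp (ps).
#' @param dt Time step (ps).
#' @param n_traj Trajectories per process.
#' @param seed Master seed; per-process seeds are derived from it.
#' @param n_boot Bootstrap resamples for the errors.
#' @param friction Langevin friction (ps^-1).
#' @param n_equil Equilibration steps before each process.
#' @return List with the three process estimates (`dF_A` etc. with
#'   errors), the assembled `dF` and `sigma`, the profile of process B,
#'   the measured [correction_inputs()] with `dF_V`/`dF_R`, the oracle
#'   result, and the closure discrepancy with its combined error.
#' @export
run_toy_cycle <- function(spec = toy_dimer_spec(beads = 1),
                          unbound = 9, bound_target = 3.4,
                          k = 50, k_floor = 0.5,
                          v_pull = 0.02, release_time = 50,
                          dt = 0.002, n_traj = 40, seed = 1,
                          n_boot = 500, friction = 5,
                          n_equil = 5000) {
  temperature <- spec$temperature
  stopifnot(k_floor > 0, v_pull > 0)

  ## process B: restrained pull from `unbound` to `bound_target`
  toyu <- make_toy_dimer(spec, separation = unbound, k = k)
  schB <- smd_schedule("center", lambda0 = unbound, v = -v_pull,
                       duration = (unbound - bound_target) / v_pull)
  outB <- run_smd(toyu$system, toyu$restraints, schB, dt = dt,
                  seed = seed + 202, n_traj = n_traj,
                  temperature = temperature, friction = friction,
                  n_equil = n_equil)
  prof <- build_profile(outB$traces, temperature, n_boot = n_boot,
                        seed = seed + 1)
  mn <- profile_minimum(prof)
  bound <- mn$lambda

  ## process A: release all restraints at the unbound separation
  schR <- smd_schedule("force_constant", lambda0 = k,
                       v = -(k - k_floor) / release_time,
                       duration = release_time)
  outA <- run_smd(toyu$system, toyu$restraints, schR, dt = dt,
                  seed = seed + 101, n_traj = n_traj,
                  temperature = temperature, friction = friction,
                  n_equil = n_equil)
  dF_A <- jarzynski_estimate(outA$works, temperature)
  s_A <- bootstrap_error(outA$works, temperature, n_boot = n_boot,
                         seed = seed + 2)

  ## process C: release all restraints at the bound separation
  toyb <- make_toy_dimer(spec, separation = bound, k = k)
  outC <- run_smd(toyb$system, toyb$restraints, schR, dt = dt,
                  seed = seed + 303, n_traj = n_traj,
                  temperature = temperature, friction = friction,
                  n_equil = n_equil)
  dF_C <- jarzynski_estimate(outC$works, temperature)
  s_C <- bootstrap_error(outC$works, temperature, n_boot = n_boot,
                         seed = seed + 3)

  ## correction inputs from restrained equilibrium runs (plus an
  ## unrestrained-bound run for r_b)
  equ <- run_equilibrium(toyu$system, toyu$restraints, dt = dt,
                         n_steps = 20000, seed = seed + 404,
                         n_traj = min(n_traj, 8),
                         temperature = temperature, friction = friction,
                         n_equil = n_equil, stride = 20)
  eqb <- run_equilibrium(toyb$system, toyb$restraints, dt = dt,
                         n_steps = 20000, seed = seed + 505,
                         n_traj = min(n_traj, 8),
                         temperature = temperature, friction = friction,
                         n_equil = n_equil, stride = 20)
  rsf <- toyb$restraints
  rsf$cv_k <- k_floor
  rsf$rmsd_k <- rep(k_floor, 2)
  rsf$planar_k <- rep(k_floor, 2)
  if (!is.null(rsf$points)) rsf$points$k <- k_floor
  eqbf <- run_equilibrium(toyb$system, rsf, dt = dt, n_steps = 20000,
                          seed = seed + 606, n_traj = min(n_traj, 8),
                          temperature = temperature, friction = friction,
                          n_equil = n_equil, stride = 20)
  ci <- measure_correction_inputs(eqb$com_sep, equ$com_sep,
                                  bound_unrestrained = eqbf$com_sep,
                                  temperature = temperature)
  dF_V <- standard_state_correction(ci)
  dF_R <- rotational_correction(ci)

  dF_B <- mn$dF; s_B <- mn$err
  assembled <- -dF_A + dF_B + dF_C
  sigma <- sqrt(s_A^2 + s_B^2 + s_C^2)

  ## exact reference between the two weakly-restrained end states
  U <- toy_cv_potential(toyu$system)
  pad <- 8 * sqrt(kBT(temperature) / k_floor)
  win <- c(0.4 * spec$sigma, unbound + pad)
  oracle <- exact_free_energy_1d(
    list(bound = function(x) U(x) + 0.5 * k_floor * (x - bound)^2,
         unbound = function(x) U(x) + 0.5 * k_floor * (x - unbound)^2),
    temperature = temperature,
    bound_window = win, unbound_window = win
  )
  disc <- assembled - oracle$dF
  list(
    dF_A = dF_A, s_A = s_A, dF_B = dF_B, s_B = s_B,
    dF_C = dF_C, s_C = s_C,
    bound_distance = bound, profile = prof,
    assembled = assembled, sigma = sigma,
    corrections = ci, dF_V = dF_V, dF_R = dF_R,
    oracle = oracle, discrepancy = disc,
    combined_error = sigma + oracle$error
  )
}
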