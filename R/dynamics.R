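# Langevin dynamics (BAOAB splitting) for toy dimer systems.
#
# Work accounting uses the discrete-protocol convention: at every step the
# driven parameter jumps from lambda_old to lambda_new at fixed
# coordinates, accumulating W += V(x; lambda_new) - V(x; lambda_old), and
# the system is then propagated one step at the new parameter value. For
# centre steering the increment equals -k (xi - lambda) v dt to first
# order in dt; for force-constant steering it equals
# (1/2) (xi - lambda)^2 dk summed over the ramped restraints.

#' Create a simulation state
#'
#' @param positions n x 3 coordinate matrix (Angstrom).
#' @param velocities n x 3 velocity matrix (A/ps); defaults to zero.
#' @param time Current time (ps).
#' @param work Accumulated external work (kcal/mol); 0 at t = 0.
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(positions, velocities = NULL, time = 0, work = 0) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  if (time == 0 && work != 0)
    stop("invalid state: work must be 0 at t = 0")
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 time = time, work = work), class = "sim_state")
}

# deterministic seed mixing; all arguments < 2^31, result in [1, 2^31-2]
.mix_seed <- function(a, b, c) {
  ((a %% 2147483647) * 1000003 + b * 7919 + c * 104729) %% 2147483629 + 1
}

# Chunked per-trajectory noise provider. Trajectory `id` always sees the
# same stream for a given master seed, independent of ensemble size.
.noise_provider <- function(master_seed, traj_ids, ndof, chunk = 4096L) {
  cache_idx <- -1L
  cache <- NULL
  m <- length(traj_ids)
  function(global_step) {
    ci <- (global_step - 1L) %/% chunk
    if (ci != cache_idx) {
      arr <- array(0, dim = c(ndof, chunk, m))
      for (t in seq_len(m)) {
        set.seed(.mix_seed(master_seed, traj_ids[t], ci))
        arr[, , t] <- rnorm(ndof * chunk)
      }
      cache <<- arr
      cache_idx <<- ci
    }
    s <- (global_step - 1L) %% chunk + 1L
    t(cache[, s, , drop = TRUE])  # m x ndof (drops to ndof x m first)
  }
}

# Maxwell-Boltzmann initial velocities, one stream per trajectory
.init_velocities <- function(master_seed, traj_ids, masses, temperature) {
  m <- length(traj_ids); n <- length(masses)
  sd_v <- sqrt(.ACC * .kB * temperature / masses)
  V <- array(0, dim = c(m, n, 3))
  for (t in seq_len(m)) {
    set.seed(.mix_seed(master_seed + 1, traj_ids[t], 0))
    V[t, , ] <- matrix(rnorm(3 * n), n, 3) * sd_v
  }
  V
}

#' One Langevin (BAOAB) integration step
#'
#' Advances a [sim_state()] by `dt` under the total force (physical plus
#' restraint, schedules evaluated at the state's clock). With
#' `friction = 0` and `temperature = 0` the update reduces to velocity
#' Verlet. Randomness is drawn from R's global RNG stream; call
#' `set.seed()` beforehand for bit-identical trajectories.
#'
#' @param state A [sim_state()].
#' @param system A [toy_system()].
#' @param restraints A [restraint_set()] (its `schedule`, if any, drives
#'   the work accumulation).
#' @param dt Time step (ps), > 0.
#' @param friction Langevin friction (ps^-1), >= 0.
#' @param temperature Temperature (K), >= 0.
#' @return The advanced `sim_state`.
#' @export
step_langevin <- function(state, system, restraints, dt,
                          friction = 5, temperature = 298) {
  if (dt <= 0) stop("configuration error: dt must be > 0")
  if (friction < 0 || temperature < 0)
    stop("configuration error: friction and temperature must be >= 0")
  n <- nrow(state$positions)
  X <- matrix(state$positions[, 1], 1); Y <- matrix(state$positions[, 2], 1)
  Z <- matrix(state$positions[, 3], 1)
  VX <- matrix(state$velocities[, 1], 1); VY <- matrix(state$velocities[, 2], 1)
  VZ <- matrix(state$velocities[, 3], 1)

  sch <- restraints$schedule
  par_at <- function(t) {
    cv <- restraints$cv_center; ks <- 1
    if (!is.null(sch)) {
      v <- schedule_value(sch, min(t, sch$duration))
      if (sch$what == "center") cv <- v else ks <- v / sch$lambda0
    }
    list(cv = cv, ks = ks)
  }
  p0 <- par_at(state$time)
  ev <- .ens_eval(X, Y, Z, system, restraints, p0$cv, p0$ks)
  .check_finite_forces(ev, system)

  mass <- system$masses
  c1 <- exp(-friction * dt)
  sig <- sqrt(pmax(0, 1 - c1^2)) * sqrt(.ACC * .kB * temperature / mass)
  half <- 0.5 * dt * .ACC / rep(mass, each = 1)

  VX <- VX + half * ev$FX; VY <- VY + half * ev$FY; VZ <- VZ + half * ev$FZ
  X <- X + 0.5 * dt * VX; Y <- Y + 0.5 * dt * VY; Z <- Z + 0.5 * dt * VZ
  if (friction > 0) {
    VX <- c1 * VX + rep(sig, each = 1) * matrix(rnorm(n), 1)
    VY <- c1 * VY + rep(sig, each = 1) * matrix(rnorm(n), 1)
    VZ <- c1 * VZ + rep(sig, each = 1) * matrix(rnorm(n), 1)
  }
  X <- X + 0.5 * dt * VX; Y <- Y + 0.5 * dt * VY; Z <- Z + 0.5 * dt * VZ

  t_new <- state$time + dt
  p1 <- par_at(t_new)
  ev2 <- .ens_eval(X, Y, Z, system, restraints, p1$cv, p1$ks)
  .check_finite_forces(ev2, system)
  work_inc <- 0
  if (!is.null(sch)) {
    if (sch$what == "center") {
      k <- restraints$cv_k * p1$ks
      work_inc <- 0.5 * k * ((ev2$xi - p1$cv)^2 - (ev2$xi - p0$cv)^2)
    } else {
      work_inc <- (p1$ks - p0$ks) * ev2$e_restr_unit
    }
  }
  VX <- VX + half * ev2$FX; VY <- VY + half * ev2$FY; VZ <- VZ + half * ev2$FZ

  sim_state(cbind(X[1, ], Y[1, ], Z[1, ]), cbind(VX[1, ], VY[1, ], VZ[1, ]),
            time = t_new, work = state$work + drop(work_inc))
}

.check_finite_forces <- function(ev, system) {
  bad <- !is.finite(ev$FX) | !is.finite(ev$FY) | !is.finite(ev$FZ)
  if (any(bad)) {
    bead <- which(colSums(bad) > 0)[1]
    stop(sprintf("numerical blow-up: non-finite force on bead %d (monomer %s)",
                 bead, system$monomer[bead]))
  }
}

# Shared ensemble propagator behind run_smd() and run_equilibrium().
.run_ensemble <- function(system, restraints, schedule, dt, n_steps, seed,
                          n_traj, temperature, friction, n_equil,
                          record_every, record_com = FALSE,
                          record_frames = FALSE) {
  n <- nrow(system$positions); m <- n_traj
  traj_ids <- seq_len(m)
  X <- matrix(system$positions[, 1], m, n, byrow = TRUE)
  Y <- matrix(system$positions[, 2], m, n, byrow = TRUE)
  Z <- matrix(system$positions[, 3], m, n, byrow = TRUE)
  V0 <- .init_velocities(seed, traj_ids, system$masses, temperature)
  VX <- matrix(V0[, , 1], m, n); VY <- matrix(V0[, , 2], m, n)
  VZ <- matrix(V0[, , 3], m, n)

  noise <- .noise_provider(seed, traj_ids, 3L * n)
  mass <- system$masses
  c1 <- exp(-friction * dt)
  sig <- sqrt(pmax(0, 1 - c1^2)) * sqrt(.ACC * .kB * temperature / mass)
  sigM <- matrix(sig, m, n, byrow = TRUE)
  halfM <- matrix(0.5 * dt * .ACC / mass, m, n, byrow = TRUE)

  par_at <- function(t) {
    cv <- restraints$cv_center; ks <- 1
    if (!is.null(schedule)) {
      t_eff <- max(0, min(t, schedule$duration))
      v <- schedule_value(schedule, t_eff)
      if (schedule$what == "center") cv <- v else ks <- v / schedule$lambda0
    }
    list(cv = cv, ks = ks)
  }

  work <- numeric(m)
  total <- n_equil + n_steps
  rec_steps <- integer(0)
  if (record_every > 0) {
    rec_steps <- unique(c(seq(0L, n_steps, by = record_every), n_steps))
  }
  W_rec <- matrix(NA_real_, length(rec_steps), m)
  lam_rec <- numeric(length(rec_steps))
  t_rec <- numeric(length(rec_steps))
  com_rec <- if (record_com) vector("list", length(rec_steps)) else NULL
  frames <- if (record_frames) vector("list", length(rec_steps)) else NULL
  wI <- numeric(n); wII <- numeric(n)
  mwI <- .monomer_weights(system, "I"); mwII <- .monomer_weights(system, "II")
  wI[mwI$idx] <- mwI$w; wII[mwII$idx] <- mwII$w

  record <- function(slot, prod_step) {
    lam <- if (!is.null(schedule))
      schedule_value(schedule, min(prod_step * dt, schedule$duration))
    else restraints$cv_center
    W_rec[slot, ] <<- work
    lam_rec[slot] <<- lam
    t_rec[slot] <<- prod_step * dt
    if (record_com) {
      com_rec[[slot]] <<- cbind(drop(X %*% (wI - wII)),
                                drop(Y %*% (wI - wII)),
                                drop(Z %*% (wI - wII)))
    }
    if (record_frames)
      frames[[slot]] <<- cbind(X[1, ], Y[1, ], Z[1, ])
  }

  p <- par_at(0)
  ev <- .ens_eval(X, Y, Z, system, restraints, p$cv, p$ks)
  .check_finite_forces(ev, system)
  slot <- 1L
  if (n_equil == 0L && length(rec_steps) && rec_steps[1] == 0L) {
    record(1L, 0L); slot <- 2L
  }

  for (s in seq_len(total)) {
    prod_step <- s - n_equil          # <= 0 during equilibration
    # B (half kick with cached force)
    VX <- VX + halfM * ev$FX; VY <- VY + halfM * ev$FY; VZ <- VZ + halfM * ev$FZ
    # A
    X <- X + 0.5 * dt * VX; Y <- Y + 0.5 * dt * VY; Z <- Z + 0.5 * dt * VZ
    # O
    if (friction > 0 && temperature > 0) {
      N <- noise(s)
      VX <- c1 * VX + sigM * N[, 1:n, drop = FALSE]
      VY <- c1 * VY + sigM * N[, (n + 1):(2 * n), drop = FALSE]
      VZ <- c1 * VZ + sigM * N[, (2 * n + 1):(3 * n), drop = FALSE]
    } else if (friction > 0) {
      VX <- c1 * VX; VY <- c1 * VY; VZ <- c1 * VZ
    }
    # A
    X <- X + 0.5 * dt * VX; Y <- Y + 0.5 * dt * VY; Z <- Z + 0.5 * dt * VZ
    # parameter jump at fixed coordinates (production only)
    p_old <- p
    p <- par_at(max(0, prod_step) * dt)
    ev <- .ens_eval(X, Y, Z, system, restraints, p$cv, p$ks)
    .check_finite_forces(ev, system)
    if (prod_step >= 1 && !is.null(schedule)) {
      if (schedule$what == "center") {
        k <- restraints$cv_k * p$ks
        work <- work +
          0.5 * k * ((ev$xi - p$cv)^2 - (ev$xi - p_old$cv)^2)
      } else {
        work <- work + (p$ks - p_old$ks) * ev$e_restr_unit
      }
    }
    # B (trailing half kick)
    VX <- VX + halfM * ev$FX; VY <- VY + halfM * ev$FY; VZ <- VZ + halfM * ev$FZ

    if (prod_step >= 0 && slot <= length(rec_steps) &&
        prod_step == rec_steps[slot]) {
      record(slot, prod_step)
      slot <- slot + 1L
    }
  }

  list(X = X, Y = Y, Z = Z, VX = VX, VY = VY, VZ = VZ,
       work = work, W_rec = W_rec, lambda = lam_rec, time = t_rec,
       com = com_rec, frames = frames, xi = ev$xi)
}

#' Steered-molecular-dynamics run over an ensemble of trajectories
#'
#' Runs `n_traj` independent Langevin trajectories while one schedule
#' drives either the CV-spring centre (distance steering) or the shared
#' restraint force constant (restraint release), accumulating the
#' external work of each trajectory on a uniform grid of the driven
#' quantity.
#'
#' @inheritParams step_langevin
#' @param schedule An [smd_schedule()]; may also be carried by
#'   `restraints` (exactly one of the two).
#' @param n_steps Number of production steps; defaults to
#'   `round(duration / dt)` and must match the schedule duration.
#' @param seed Master seed. Trajectory `i` derives its own reproducible
#'   stream from `(seed, i)`.
#' @param n_traj Number of independent trajectories.
#' @param n_equil Equilibration steps at the initial parameter value
#'   before work accumulation starts.
#' @param grid_width Driven-quantity spacing of the recorded work grid
#'   (default 0.1 A for centre steering, 0.5 kcal/mol/A^2 for
#'   force-constant steering).
#' @param record_frames Record strided coordinates of trajectory 1.
#' @param record_com Record per-frame monomer-monomer COM separation
#'   components for every trajectory (used by
#'   [measure_correction_inputs()]).
#' @return List with `traces` (list of [work_trace()]), `lambda` (the
#'   common grid), `works` (final work per trajectory), and optional
#'   `frames` / `com_sep` records.
#' @examples
#' toy <- make_toy_dimer(toy_dimer_spec(beads = 1))
#' sch <- smd_schedule("center", lambda0 = toy$restraints$cv_center,
#'                     v = -2, duration = 1)
#' out <- run_smd(toy$system, toy$restraints, sch, dt = 0.002,
#'                seed = 1, n_traj = 2, n_equil = 100)
#' @export
run_smd <- function(system, restraints, schedule = NULL, dt = 0.002,
                    n_steps = NULL, seed = 1, n_traj = 1,
                    temperature = 298, friction = 5, n_equil = 0,
                    grid_width = NULL, record_frames = FALSE,
                    record_com = FALSE) {
  if (is.null(schedule)) schedule <- restraints$schedule
  else if (!is.null(restraints$schedule))
    stop("configuration error: schedule given both directly and in the restraint set")
  if (is.null(schedule))
    stop("configuration error: run_smd needs exactly one scheduled restraint")
  restraints$schedule <- NULL
  if (is.null(n_steps)) n_steps <- max(1L, round(schedule$duration / dt))
  if (abs(n_steps * dt - schedule$duration) > 1e-8 * max(1, schedule$duration))
    stop("configuration error: n_steps * dt must equal the schedule duration")
  if (is.null(grid_width))
    grid_width <- if (schedule$what == "center") 0.1 else 0.5
  record_every <- if (schedule$v == 0) max(1L, n_steps %/% 100L)
  else max(1L, round(grid_width / (abs(schedule$v) * dt)))

  out <- .run_ensemble(system, restraints, schedule, dt, n_steps, seed,
                       n_traj, temperature, friction, n_equil,
                       record_every, record_com = record_com,
                       record_frames = record_frames)
  traces <- lapply(seq_len(n_traj), function(i)
    work_trace(time = out$time, lambda = out$lambda, work = out$W_rec[, i],
               id = i))
  com_sep <- if (record_com) do.call(rbind, out$com) else NULL
  list(traces = traces, lambda = out$lambda, works = out$work,
       frames = out$frames, com_sep = com_sep, schedule = schedule,
       final = out[c("X", "Y", "Z", "VX", "VY", "VZ")],
       n_steps = n_steps, dt = dt)
}

#' Equilibrium Langevin run (no steering)
#'
#' @inheritParams run_smd
#' @param n_steps Number of production steps.
#' @param stride Recording stride in steps.
#' @return List with `com_sep` (pooled (frames x trajectories) x 3 matrix
#'   of monomer-monomer COM separation components), `frames` (strided
#'   coordinates of trajectory 1) and the final ensemble state.
#' @export
run_equilibrium <- function(system, restraints, dt = 0.002, n_steps = 1000,
                            seed = 1, n_traj = 1, temperature = 298,
                            friction = 5, n_equil = 0, stride = 10) {
  restraints$schedule <- NULL
  out <- .run_ensemble(system, restraints, NULL, dt, n_steps, seed,
                       n_traj, temperature, friction, n_equil,
                       record_every = stride, record_com = TRUE,
                       record_frames = TRUE)
  list(com_sep = do.call(rbind, out$com), frames = out$frames,
       time = out$time,
       final = out[c("X", "Y", "Z", "VX", "VY", "VZ")])
}
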