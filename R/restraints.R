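#' Steering schedule for one driven restraint quantity
#'
#' The driven quantity moves linearly in time, `lambda(t) = lambda0 + v t`.
#' `"center"` schedules drive the centre of the collective-variable spring
#' (standard distance steering); `"force_constant"` schedules drive the
#' force constant shared by every restraint (the restraint-release
#' processes), scaling each restraint's `k` by `lambda(t)/lambda0`.
#'
#' @param what `"center"` or `"force_constant"`.
#' @param lambda0 Initial value of the driven quantity (Angstrom, or
#'   kcal/mol/A^2 for force-constant steering).
#' @param v Steering velocity (driven units per ps); may be negative.
#' @param duration Schedule duration (ps), > 0.
#' @return An object of class `smd_schedule`.
#' @examples
#' smd_schedule("center", lambda0 = 9, v = -0.02, duration = 280)
#' @export
smd_schedule <- function(what = c("center", "force_constant"),
                         lambda0, v, duration) {
  what <- match.arg(what)
  stopifnot(is.numeric(lambda0), is.numeric(v), is.numeric(duration))
  if (duration <= 0) stop("configuration error: schedule duration must be > 0")
  if (what == "force_constant" && lambda0 <= 0)
    stop("configuration error: force-constant schedule needs lambda0 > 0")
  structure(list(what = what, lambda0 = lambda0, v = v, duration = duration),
            class = "smd_schedule")
}

#' Evaluate a schedule at time t
#' @param schedule An [smd_schedule()].
#' @param t Time (ps).
#' @return The driven-quantity value `lambda0 + v t`.
#' @export
schedule_value <- function(schedule, t) schedule$lambda0 + schedule$v * t

#' The eleven-restraint vocabulary of the confinement cycle
#'
#' Assembles the restraint set used throughout: one collective-variable
#' spring on the monomer-monomer COM X-distance, one structure (RMSD)
#' restraint per monomer, one planar (COM y/z) restraint per monomer, six
#' single-bead point restraints that pin the orientation of the monomers,
#' and an optional flat-bottom umbrella on the 3-D COM separation.
#'
#' Point restraint types: `"line"` fixes y and z of a bead (an axis fix),
#' `"zfix"` fixes z only (bead held on an X-Y plane), `"yfix"` fixes y
#' only (bead held on an X-Z plane).
#'
#' @param cv_k Spring constant of the CV spring (kcal/mol/A^2).
#' @param cv_center Spring centre (Angstrom).
#' @param rmsd_k Length-2 vector: structure-restraint constants for
#'   monomers I and II (kcal/mol/A^2, applied to the mean-square deviation
#'   from centred reference coordinates).
#' @param planar_k Length-2 vector: planar restraint constants.
#' @param planar_targets 2 x 2 matrix, rows = monomers I/II, columns =
#'   target y and z of the monomer COM (Angstrom).
#' @param points Data frame with columns `bead`, `type`
#'   (line/zfix/yfix), `k`, `y0`, `z0`.
#' @param flat_bottom `NULL`, or `list(k, r1, r2, r3, r4)` with ordered
#'   knots; zero inside `[r2, r3]`, harmonic on `[r1, r2]` and `[r3, r4]`,
#'   linear with matched slope beyond `r1`/`r4`.
#' @param schedule Optional [smd_schedule()] carried by the set (at most
#'   one schedule per run).
#' @return An object of class `restraint_set`.
#' @export
restraint_set <- function(cv_k = 50, cv_center = 0,
                          rmsd_k = c(0, 0),
                          planar_k = c(0, 0),
                          planar_targets = matrix(0, 2, 2),
                          points = NULL,
                          flat_bottom = NULL,
                          schedule = NULL) {
  rmsd_k <- rep_len(rmsd_k, 2L)
  planar_k <- rep_len(planar_k, 2L)
  planar_targets <- matrix(planar_targets, 2, 2)
  if (cv_k < 0 || any(rmsd_k < 0) || any(planar_k < 0))
    stop("configuration error: force constants must be >= 0")
  if (!is.null(points)) {
    points <- as.data.frame(points)
    stopifnot(all(c("bead", "type", "k") %in% names(points)))
    if (!all(points$type %in% c("line", "zfix", "yfix")))
      stop("configuration error: unknown point-restraint type")
    if (any(points$k < 0))
      stop("configuration error: force constants must be >= 0")
    if (is.null(points$y0)) points$y0 <- 0
    if (is.null(points$z0)) points$z0 <- 0
  }
  if (!is.null(flat_bottom)) {
    kn <- unlist(flat_bottom[c("r1", "r2", "r3", "r4")])
    if (length(kn) != 4L || is.unsorted(kn))
      stop("configuration error: flat-bottom knots must satisfy r1 <= r2 <= r3 <= r4")
    if (flat_bottom$k < 0)
      stop("configuration error: force constants must be >= 0")
  }
  if (!is.null(schedule) && !inherits(schedule, "smd_schedule"))
    stop("configuration error: 'schedule' must be an smd_schedule")
  structure(list(
    cv_k = cv_k, cv_center = cv_center,
    rmsd_k = rmsd_k, planar_k = planar_k, planar_targets = planar_targets,
    points = points, flat_bottom = flat_bottom, schedule = schedule
  ), class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("restraint_set:\n")
  cat(sprintf("  CV spring: k = %g, center = %g A\n", x$cv_k, x$cv_center))
  cat(sprintf("  structure (RMSD) k: %g / %g; planar k: %g / %g\n",
              x$rmsd_k[1], x$rmsd_k[2], x$planar_k[1], x$planar_k[2]))
  cat("  point restraints:", if (is.null(x$points)) 0 else nrow(x$points), "\n")
  if (!is.null(x$flat_bottom))
    cat(sprintf("  flat-bottom: k = %g, knots %s\n", x$flat_bottom$k,
                paste(unlist(x$flat_bottom[c("r1","r2","r3","r4")]), collapse = ", ")))
  if (!is.null(x$schedule))
    cat(sprintf("  scheduled: %s, lambda0 = %g, v = %g, duration = %g ps\n",
                x$schedule$what, x$schedule$lambda0, x$schedule$v,
                x$schedule$duration))
  invisible(x)
}

#' Number of restraints in a set
#' @param restraints A [restraint_set()].
#' @return Integer count (CV spring + structure + planar + point +
#'   flat-bottom terms with non-zero bookkeeping presence).
#' @export
restraint_census <- function(restraints) {
  n <- 0L
  if (restraints$cv_k > 0) n <- n + 1L
  n <- n + sum(restraints$rmsd_k > 0) + sum(restraints$planar_k > 0)
  if (!is.null(restraints$points)) n <- n + nrow(restraints$points)
  if (!is.null(restraints$flat_bottom)) n <- n + 1L
  n
}

# flat-bottom umbrella: value and derivative on a numeric vector r
.flat_bottom_u <- function(r, k, r1, r2, r3, r4) {
  u <- numeric(length(r)); du <- numeric(length(r))
  lo <- r < r1
  u[lo] <- 0.5 * k * (r1 - r2)^2 + k * (r1 - r2) * (r[lo] - r1)
  du[lo] <- k * (r1 - r2)
  a <- !lo & r < r2
  u[a] <- 0.5 * k * (r[a] - r2)^2; du[a] <- k * (r[a] - r2)
  b <- r > r3 & r <= r4
  u[b] <- 0.5 * k * (r[b] - r3)^2; du[b] <- k * (r[b] - r3)
  hi <- r > r4
  u[hi] <- 0.5 * k * (r4 - r3)^2 + k * (r4 - r3) * (r[hi] - r4)
  du[hi] <- k * (r4 - r3)
  list(u = u, du = du)
}

# Ensemble energy/force evaluation.
# X, Y, Z: m x n matrices (m replicas, n beads). Returns total potential
# and forces plus the restraint energy at unit force-constant scale
# (needed for force-constant steering work) and the CV value.
.ens_eval <- function(X, Y, Z, system, rs, cv_center, k_scale = 1,
                      physical = TRUE) {
  m <- nrow(X); n <- ncol(X)
  FX <- matrix(0, m, n); FY <- matrix(0, m, n); FZ <- matrix(0, m, n)
  mwI <- .monomer_weights(system, "I"); mwII <- .monomer_weights(system, "II")
  wI <- numeric(n); wI[mwI$idx] <- mwI$w
  wII <- numeric(n); wII[mwII$idx] <- mwII$w
  wD <- wI - wII

  e_phys <- numeric(m); e_restr <- numeric(m)

  ## --- physical terms -----------------------------------------------------
  bonds <- if (physical) system$bonds else NULL
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      dx <- X[, i] - X[, j]; dy <- Y[, i] - Y[, j]; dz <- Z[, i] - Z[, j]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      e_phys <- e_phys + 0.5 * bonds$k[b] * (r - bonds$r0[b])^2
      f <- bonds$k[b] * (r - bonds$r0[b]) / pmax(r, 1e-12)
      FX[, i] <- FX[, i] - f * dx; FX[, j] <- FX[, j] + f * dx
      FY[, i] <- FY[, i] - f * dy; FY[, j] <- FY[, j] + f * dy
      FZ[, i] <- FZ[, i] - f * dz; FZ[, j] <- FZ[, j] + f * dz
    }
  }

  dcom <- drop(X %*% wD)                      # signed COM x-separation
  s <- ifelse(dcom >= 0, 1, -1)
  xi <- abs(dcom)

  eps <- system$epsilon; sig <- system$sigma
  if (!physical) {
    # restraint-only evaluation: skip interaction terms
  } else if (system$interface == "axial") {
    sr6 <- (sig / xi)^6
    e_phys <- e_phys + 4 * eps * (sr6^2 - sr6)
    dUdxi <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / xi
    g <- dUdxi * s
    FX <- FX - tcrossprod(g, wD)
  } else {
    q <- system$charges
    for (i in mwI$idx) for (j in mwII$idx) {
      dx <- X[, i] - X[, j]; dy <- Y[, i] - Y[, j]; dz <- Z[, i] - Z[, j]
      r2 <- dx^2 + dy^2 + dz^2; r <- sqrt(r2)
      sr6 <- (sig^2 / r2)^3
      e_phys <- e_phys + 4 * eps * (sr6^2 - sr6)
      dUdr <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r
      if (!is.null(q)) {
        e_phys <- e_phys + 332.0636 * q[i] * q[j] / r
        dUdr <- dUdr - 332.0636 * q[i] * q[j] / r2
      }
      f <- dUdr / r
      FX[, i] <- FX[, i] - f * dx; FX[, j] <- FX[, j] + f * dx
      FY[, i] <- FY[, i] - f * dy; FY[, j] <- FY[, j] + f * dy
      FZ[, i] <- FZ[, i] - f * dz; FZ[, j] <- FZ[, j] + f * dz
    }
  }

  ## --- restraint terms (all scaled by k_scale) ----------------------------
  # CV spring
  if (rs$cv_k > 0) {
    k <- k_scale * rs$cv_k
    dev <- xi - cv_center
    e_restr <- e_restr + 0.5 * k * dev^2
    FX <- FX - tcrossprod(k * dev * s, wD)
  }
  # structure (centred mean-square-deviation) restraints
  for (mi in 1:2) {
    k <- k_scale * rs$rmsd_k[mi]
    if (k <= 0) next
    idx <- if (mi == 1) mwI$idx else mwII$idx
    nm <- length(idx)
    ax <- system$reference[idx, 1] - mean(system$reference[idx, 1])
    ay <- system$reference[idx, 2] - mean(system$reference[idx, 2])
    az <- system$reference[idx, 3] - mean(system$reference[idx, 3])
    Xs <- X[, idx, drop = FALSE]; Ys <- Y[, idx, drop = FALSE]
    Zs <- Z[, idx, drop = FALSE]
    dxm <- Xs - rowMeans(Xs) - rep(ax, each = m)
    dym <- Ys - rowMeans(Ys) - rep(ay, each = m)
    dzm <- Zs - rowMeans(Zs) - rep(az, each = m)
    e_restr <- e_restr + 0.5 * k * rowSums(dxm^2 + dym^2 + dzm^2) / nm
    FX[, idx] <- FX[, idx] - (k / nm) * dxm
    FY[, idx] <- FY[, idx] - (k / nm) * dym
    FZ[, idx] <- FZ[, idx] - (k / nm) * dzm
  }
  # planar (monomer COM y/z) restraints
  for (mi in 1:2) {
    k <- k_scale * rs$planar_k[mi]
    if (k <= 0) next
    wM <- if (mi == 1) wI else wII
    dy <- drop(Y %*% wM) - rs$planar_targets[mi, 1]
    dz <- drop(Z %*% wM) - rs$planar_targets[mi, 2]
    e_restr <- e_restr + 0.5 * k * (dy^2 + dz^2)
    FY <- FY - tcrossprod(k * dy, wM)
    FZ <- FZ - tcrossprod(k * dz, wM)
  }
  # single-bead point restraints
  pts <- rs$points
  if (!is.null(pts) && nrow(pts) > 0) {
    for (p in seq_len(nrow(pts))) {
      k <- k_scale * pts$k[p]
      if (k <= 0) next
      b <- pts$bead[p]
      if (pts$type[p] %in% c("line", "yfix")) {
        dy <- Y[, b] - pts$y0[p]
        e_restr <- e_restr + 0.5 * k * dy^2
        FY[, b] <- FY[, b] - k * dy
      }
      if (pts$type[p] %in% c("line", "zfix")) {
        dz <- Z[, b] - pts$z0[p]
        e_restr <- e_restr + 0.5 * k * dz^2
        FZ[, b] <- FZ[, b] - k * dz
      }
    }
  }
  # flat-bottom umbrella on the 3-D COM separation
  fb <- rs$flat_bottom
  if (!is.null(fb) && fb$k > 0) {
    dX <- dcom
    dY <- drop(Y %*% wD); dZ <- drop(Z %*% wD)
    R <- sqrt(dX^2 + dY^2 + dZ^2)
    u <- .flat_bottom_u(R, k_scale * fb$k, fb$r1, fb$r2, fb$r3, fb$r4)
    e_restr <- e_restr + u$u
    g <- u$du / pmax(R, 1e-12)
    FX <- FX - tcrossprod(g * dX, wD)
    FY <- FY - tcrossprod(g * dY, wD)
    FZ <- FZ - tcrossprod(g * dZ, wD)
  }

  list(energy = e_phys + e_restr, e_phys = e_phys, e_restr = e_restr,
       e_restr_unit = e_restr / k_scale, xi = xi,
       FX = FX, FY = FY, FZ = FZ)
}

#' Restraint energy and exact forces at a configuration
#'
#' Evaluates every active restraint at time `t` (schedules resolved) and
#' returns the total restraint energy together with the per-bead forces,
#' which are the exact negative gradients of the energy.
#'
#' @param system A [toy_system()].
#' @param restraints A [restraint_set()].
#' @param t Time (ps) at which any attached schedule is evaluated.
#' @param positions Optional coordinates overriding the system's.
#' @return List with `energy` (kcal/mol), `forces` (n x 3 matrix,
#'   kcal/mol/A), `cv` (the collective-variable value), `cv_center` and
#'   `k_scale` actually applied.
#' @examples
#' toy <- make_toy_dimer(toy_dimer_spec())
#' restraint_energy(toy$system, toy$restraints)$energy
#' @export
restraint_energy <- function(system, restraints, t = 0, positions = NULL) {
  xyz <- if (is.null(positions)) system$positions else as.matrix(positions)
  cv_center <- restraints$cv_center
  k_scale <- 1
  sch <- restraints$schedule
  if (!is.null(sch)) {
    if (sch$what == "center") cv_center <- schedule_value(sch, t)
    else k_scale <- schedule_value(sch, t) / sch$lambda0
  }
  ev <- .ens_eval(matrix(xyz[, 1], 1), matrix(xyz[, 2], 1), matrix(xyz[, 3], 1),
                  system, restraints, cv_center, k_scale, physical = FALSE)
  list(energy = ev$e_restr[1],
       forces = cbind(ev$FX[1, ], ev$FY[1, ], ev$FZ[1, ]),
       cv = ev$xi[1], cv_center = cv_center, k_scale = k_scale)
}

#' Total potential energy (physical + restraint) and forces
#'
#' @inheritParams restraint_energy
#' @return List with `energy`, `e_phys`, `e_restr`, `forces` (n x 3), `cv`.
#' @export
potential_energy <- function(system, restraints, t = 0, positions = NULL) {
  xyz <- if (is.null(positions)) system$positions else as.matrix(positions)
  cv_center <- restraints$cv_center
  k_scale <- 1
  sch <- restraints$schedule
  if (!is.null(sch)) {
    if (sch$what == "center") cv_center <- schedule_value(sch, t)
    else k_scale <- schedule_value(sch, t) / sch$lambda0
  }
  ev <- .ens_eval(matrix(xyz[, 1], 1), matrix(xyz[, 2], 1), matrix(xyz[, 3], 1),
                  system, restraints, cv_center, k_scale)
  list(energy = ev$energy[1], e_phys = ev$e_phys[1], e_restr = ev$e_restr[1],
       forces = cbind(ev$FX[1, ], ev$FY[1, ], ev$FZ[1, ]), cv = ev$xi[1])
}
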