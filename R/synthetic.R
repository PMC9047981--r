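# Synthetic study systems: toy dimers with known binding thermodynamics,
# exact quadrature oracles, and structure fixtures with planted
# interaction geometry.

#' Specification of a toy dimer
#'
#' @param beads Beads per monomer (>= 1).
#' @param epsilon Interface well depth (kcal/mol).
#' @param sigma Interface length scale (Angstrom).
#' @param bond_k Intra-monomer harmonic bond constant (kcal/mol/A^2).
#' @param mass Bead mass (amu).
#' @param temperature Temperature (K).
#' @param seed Seed for the deterministic geometry jitter.
#' @return An object of class `toy_dimer_spec`.
#' @export
toy_dimer_spec <- function(beads = 3, epsilon = 3, sigma = 3,
                           bond_k = 100, mass = 12, temperature = 298,
                           seed = 1) {
  if (beads < 1 || epsilon <= 0 || sigma <= 0 || mass <= 0)
    stop("invalid toy spec: beads >= 1 and positive epsilon/sigma/mass required")
  structure(list(beads = beads, epsilon = epsilon, sigma = sigma,
                 bond_k = bond_k, mass = mass, temperature = temperature,
                 seed = seed), class = "toy_dimer_spec")
}

# ring of `b` beads around a monomer centre; COM sits exactly on centre
.monomer_beads <- function(b, center_x, radius = 1) {
  if (b == 1) return(matrix(c(center_x, 0, 0), 1, 3))
  ang <- 2 * pi * (seq_len(b) - 1) / b
  cbind(center_x + radius * cos(ang) - mean(radius * cos(ang)),
        radius * sin(ang) - mean(radius * sin(ang)),
        rep(0, b))
}

#' Build a toy dimer with the full eleven-restraint scheme
#'
#' Constructs a two-monomer bead system and its restraint set: one CV
#' spring on the monomer COM X-distance, two structure (centred MSD)
#' restraints, two planar COM restraints, and six single-bead point
#' restraints pinning the orientation (one axis fix, one X-Y-plane fix
#' and one X-Z-plane fix per monomer). Deterministic for a fixed seed.
#'
#' @param spec A [toy_dimer_spec()].
#' @param separation Initial monomer COM X-distance (Angstrom); also the
#'   initial CV-spring centre.
#' @param k Restraint force constant applied to every restraint
#'   (kcal/mol/A^2).
#' @return List with `system` ([toy_system()]), `restraints`
#'   ([restraint_set()]) and `spec`.
#' @examples
#' toy <- make_toy_dimer(toy_dimer_spec())
#' restraint_census(toy$restraints) # 11
#' @export
make_toy_dimer <- function(spec, separation = 9, k = 50) {
  stopifnot(inherits(spec, "toy_dimer_spec"))
  b <- spec$beads
  set.seed(spec$seed)
  p1 <- .monomer_beads(b, 0)
  p2 <- .monomer_beads(b, separation)
  jit <- matrix(stats::runif(6 * b, -0.01, 0.01), 2 * b, 3)
  pos <- rbind(p1, p2) + jit
  monomer <- rep(c("I", "II"), each = b)
  masses <- rep(spec$mass, 2 * b)
  # recentre each monomer COM onto the X axis at the prescribed spacing
  for (mi in c("I", "II")) {
    idx <- monomer == mi
    com <- colMeans(pos[idx, , drop = FALSE])
    tgt <- c(if (mi == "I") 0 else separation, 0, 0)
    pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, com - tgt)
  }
  bonds <- NULL
  if (b >= 2) {
    mk <- function(off) {
      i <- off + seq_len(b)
      j <- off + c(seq_len(b - 1) + 1, 1)
      keep <- if (b == 2) 1L else seq_len(b)
      data.frame(i = i[keep], j = j[keep], k = spec$bond_k,
                 r0 = sqrt(rowSums((pos[i[keep], , drop = FALSE] -
                                      pos[j[keep], , drop = FALSE])^2)))
    }
    bonds <- rbind(mk(0L), mk(b))
  }
  sys <- toy_system(pos, masses, monomer, epsilon = spec$epsilon,
                    sigma = spec$sigma, bonds = bonds, reference = pos,
                    interface = "axial")
  tag <- function(off) off + pmin(1:3, b)
  pts <- data.frame(
    bead = c(tag(0L), tag(b)),
    type = rep(c("line", "zfix", "yfix"), 2),
    k = k,
    y0 = pos[c(tag(0L), tag(b)), 2],
    z0 = pos[c(tag(0L), tag(b)), 3]
  )
  rs <- restraint_set(
    cv_k = k, cv_center = separation,
    rmsd_k = c(k, k), planar_k = c(k, k),
    planar_targets = matrix(0, 2, 2),
    points = pts
  )
  list(system = sys, restraints = rs, spec = spec)
}

#' Interface potential of a toy dimer as a 1-D function
#'
#' The axial Lennard-Jones interface of a toy dimer evaluated on the
#' collective variable, optionally plus a harmonic spring `k/2 (x-c)^2`
#' (the residual CV restraint of a given state). This is the potential
#' handed to the quadrature oracles.
#'
#' @param system A [toy_system()] with `interface = "axial"`.
#' @param k,center Optional CV spring added to the interface term.
#' @return A function of the CV value (Angstrom) returning kcal/mol.
#' @export
toy_cv_potential <- function(system, k = 0, center = 0) {
  eps <- system$epsilon; sig <- system$sigma
  function(x) {
    sr6 <- (sig / x)^6
    4 * eps * (sr6^2 - sr6) + 0.5 * k * (x - center)^2
  }
}

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

# -kBT log of the configurational integral of exp(-U/kBT) over [lo, hi]
.logZ <- function(fn, lo, hi, n, b) {
  x <- seq(lo, hi, length.out = n)
  u <- fn(x)
  u0 <- min(u)
  log(.trapz(x, exp(-b * (u - u0)))) - b * u0
}

#' Exact binding free energy of a 1-D potential by quadrature
#'
#' Reference oracle: the free-energy difference between a bound and an
#' unbound window of a one-dimensional potential,
#' `dF = -kBT log( Z_bound / Z_unbound )`, with Richardson-extrapolated
#' trapezoidal quadrature and an estimated numerical error. When
#' `standard_volume` is given, the standard-state term
#' `+ kBT log(standard_volume / width(unbound_window))` referencing the
#' unbound state to that volume is added.
#'
#' The potential may be a function, a two-column table `(r, U)`, or a
#' list `list(bound = , unbound = )` of either, for states that differ
#' by more than the window (e.g. residual restraint springs centred at
#' different positions).
#'
#' @param potential See Details.
#' @param temperature Temperature (K).
#' @param bound_window,unbound_window Length-2 numeric `c(lo, hi)`.
#' @param standard_volume Optional standard length (1-D volume) for the
#'   unbound reference state.
#' @param tol Requested quadrature accuracy (kcal/mol).
#' @return List of class `oracle_result`: `dF` (kcal/mol), `method`
#'   (`"quadrature"`), `error` (estimated numerical error).
#' @examples
#' flat <- function(x) rep(0, length(x))
#' exact_free_energy_1d(flat, 298, c(0, 1), c(2, 3))$dF # 0
#' @export
exact_free_energy_1d <- function(potential, temperature = 298,
                                 bound_window, unbound_window,
                                 standard_volume = NULL, tol = 1e-8) {
  b <- 1 / kBT(temperature)
  as_fn <- function(p) {
    if (is.function(p)) return(p)
    p <- as.matrix(p)
    stats::splinefun(p[, 1], p[, 2])
  }
  if (is.list(potential) && !is.function(potential) &&
      all(c("bound", "unbound") %in% names(potential))) {
    fb <- as_fn(potential$bound); fu <- as_fn(potential$unbound)
  } else {
    fb <- fu <- as_fn(potential)
  }
  dF_at <- function(n) {
    kBT(temperature) *
      (.logZ(fu, unbound_window[1], unbound_window[2], n, b) -
         .logZ(fb, bound_window[1], bound_window[2], n, b))
  }
  n <- 1025L
  prev <- dF_at(n)
  err <- Inf; val <- prev
  for (iter in 1:10) {
    n <- 2L * (n - 1L) + 1L
    cur <- dF_at(n)
    err <- abs(cur - prev) / 3
    val <- cur + (cur - prev) / 3
    if (is.finite(err) && err < tol) break
    prev <- cur
  }
  if (!is.finite(err) || err > max(tol, 1e-3))
    stop("resolution error: quadrature did not converge on this grid")
  if (!is.null(standard_volume)) {
    Lu <- diff(unbound_window)
    val <- val + kBT(temperature) * log(standard_volume / Lu)
  }
  structure(list(dF = val, method = "quadrature", error = err),
            class = "oracle_result")
}

#' Exact restrained free-energy profile (PMF) by quadrature
#'
#' The free energy of a 1-D potential under a harmonic spring of
#' constant `k` as a function of the spring centre, relative to the
#' first centre: the converged-pulling reference for
#' [build_profile()].
#'
#' @param potential Function of the coordinate (kcal/mol).
#' @param k Spring constant (kcal/mol/A^2).
#' @param centers Spring-centre grid (Angstrom).
#' @param temperature Temperature (K).
#' @param window Integration window; defaults to the centre range
#'   padded by 6 thermal spring widths.
#' @param n Quadrature points.
#' @return Data frame with `lambda` and `dF` (zero at the first
#'   centre).
#' @export
pmf_oracle_1d <- function(potential, k, centers, temperature = 298,
                          window = NULL, n = 8193L) {
  b <- 1 / kBT(temperature)
  if (is.null(window)) {
    w <- 6 * sqrt(kBT(temperature) / k)
    window <- c(min(centers) - w, max(centers) + w)
    window[1] <- max(window[1], 1e-3)
  }
  lz <- vapply(centers, function(cc)
    .logZ(function(x) potential(x) + 0.5 * k * (x - cc)^2,
          window[1], window[2], n, b), numeric(1))
  dF <- -kBT(temperature) * lz
  data.frame(lambda = centers, dF = dF - dF[1])
}

#' Analytic free energy of changing a harmonic force constant
#'
#' Closed-form reference for the restraint-release processes: for
#' `n_dof` independent harmonic degrees of freedom whose force constant
#' moves from `k_from` to `k_to`,
#' `dF = (n_dof / 2) kB T log(k_to / k_from)`.
#' Release to exactly zero has no finite reference (a free particle is
#' not normalizable); release to a small positive floor instead.
#'
#' @param k_from,k_to Force constants (kcal/mol/A^2), > 0.
#' @param n_dof Number of degrees of freedom.
#' @param temperature Temperature (K).
#' @return Free-energy difference (kcal/mol).
#' @examples
#' harmonic_release_reference(50, 0.5) # ~ -1.364
#' @export
harmonic_release_reference <- function(k_from, k_to, n_dof = 1,
                                       temperature = 298) {
  if (k_from <= 0 || k_to <= 0)
    stop("domain error: force constants must be > 0 (no finite reference at k = 0)")
  (n_dof / 2) * kBT(temperature) * log(k_to / k_from)
}

# hexagonal aromatic ring template (radius 1.39 A) in the x-y plane,
# normal along z, centred at the origin
.ring_template <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  rownames(xyz) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  xyz
}

.atom_row <- function(eleno, name, resname, chain, resno, xyz, element) {
  data.frame(eleno = eleno, name = name, resname = resname, chain = chain,
             resno = resno, insert = "", element = element,
             x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
}

.phe_residue <- function(chain, resno, center, rot = diag(3), start_eleno = 1) {
  ring <- .ring_template() %*% t(rot)
  ring <- sweep(ring, 2, center, `+`)
  extra <- rbind(CB = c(2.90, 0, 0), CA = c(4.10, 0.80, 0),
                 N = c(5.30, 0.00, 0), C = c(4.30, 2.30, 0),
                 O = c(3.40, 3.10, 0)) %*% t(rot)
  extra <- sweep(extra, 2, center, `+`)
  at <- rbind(ring, extra)
  el <- c(rep("C", 6), "C", "C", "N", "C", "O")
  do.call(rbind, lapply(seq_len(nrow(at)), function(i)
    .atom_row(start_eleno + i - 1, rownames(at)[i], "PHE", chain, resno,
              at[i, ], el[i])))
}

# rotation by `theta` degrees about the x axis
.rot_x <- function(theta) {
  t <- theta * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

.hbond_atoms <- function(on_distance, dha_angle, acceptor_shift = c(0, 0, 0)) {
  th <- dha_angle * pi / 180
  h <- c(1.01, 0, 0)
  disc <- on_distance^2 - (1.01 * sin(th))^2
  if (disc < 0)
    stop("domain error: O-N distance incompatible with the requested angle")
  s <- 1.01 * cos(th) + sqrt(disc)
  o <- h + s * c(-cos(th), sin(th), 0)
  rbind(
    .atom_row(1, "N", "ALA", "A", 1, c(0, 0, 0), "N"),
    .atom_row(2, "H", "ALA", "A", 1, h, "H"),
    .atom_row(3, "CA", "ALA", "A", 1, c(-0.70, -1.20, 0), "C"),
    .atom_row(4, "O", "ALA", "B", 1, o + acceptor_shift, "O"),
    .atom_row(5, "C", "ALA", "B", 1, o + acceptor_shift +
                c(0, 1.23, 0), "C"),
    .atom_row(6, "CA", "ALA", "B", 1, o + acceptor_shift +
                c(1.20, 2.10, 0), "C")
  )
}

#' Structure fixtures with planted interaction geometry
#'
#' Minimal valid structures whose interaction geometry is planted
#' exactly (to the 1e-3 A PDB precision), for validating the
#' structural detectors:
#' \describe{
#'   \item{`"pipi"`}{two Phe rings on chains A/B at a prescribed
#'     ring-centre `distance` and normal-normal `angle`.}
#'   \item{`"hbond"`}{an N-H donor (chain A) and a carbonyl O acceptor
#'     (chain B) at a prescribed O-N `on_distance` and donor-H-acceptor
#'     `dha_angle`.}
#'   \item{`"burial"`}{returns `list(bound, unbound)`: a probe residue
#'     enclosed by a cage of atoms in the bound form and isolated in
#'     the unbound form (largest SASA difference by construction).}
#'   \item{`"multiframe"`}{a multi-model structure in which the planted
#'     hydrogen bond is present in `round(occupancy * n_frames)` of the
#'     frames.}
#' }
#'
#' @param kind Fixture kind (see Details).
#' @param distance Ring-centre distance for `"pipi"` (Angstrom).
#' @param angle Ring normal-normal angle for `"pipi"` (degrees).
#' @param on_distance O-N distance for `"hbond"`/`"multiframe"`.
#' @param dha_angle Donor-H-acceptor angle (degrees).
#' @param occupancy Fraction of frames with the bond present.
#' @param n_frames Number of frames for `"multiframe"`.
#' @param seed Unused randomness hook kept for interface stability;
#'   fixtures are fully deterministic.
#' @return An [md_structure()], or a list of two for `"burial"`.
#' @examples
#' nrow(detect_pipi(make_structure_fixture("pipi", distance = 4, angle = 0)))
#' @export
make_structure_fixture <- function(kind = c("pipi", "hbond", "burial",
                                            "multiframe"),
                                   distance = 4, angle = 0,
                                   on_distance = 2.8, dha_angle = 160,
                                   occupancy = 0.7, n_frames = 10,
                                   seed = 1) {
  kind <- match.arg(kind)
  if (distance <= 0 || on_distance <= 0)
    stop("domain error: planted distances must be positive")
  if (kind == "pipi") {
    a1 <- .phe_residue("A", 1, c(0, 0, 0))
    a2 <- .phe_residue("B", 1, c(0, 0, distance), rot = .rot_x(angle),
                       start_eleno = 12)
    return(md_structure(rbind(a1, a2)))
  }
  if (kind == "hbond") {
    return(md_structure(.hbond_atoms(on_distance, dha_angle)))
  }
  if (kind == "burial") {
    line <- do.call(rbind, lapply(1:3, function(i)
      .atom_row(i, "CA", "GLY", "A", i, c(0, (i - 2) * 4, 0), "C")))
    cage <- do.call(rbind, lapply(1:8, function(i) {
      s <- c(-1, 1)[c((i - 1) %% 2, (i - 1) %/% 2 %% 2,
                      (i - 1) %/% 4) + 1]
      .atom_row(3 + i, "CA", "GLY", "B", i, 2.31 * s, "C")
    }))
    bound <- md_structure(rbind(line, cage))
    cage_u <- cage
    cage_u$x <- cage_u$x + 50
    unbound <- md_structure(rbind(line, cage_u))
    return(list(bound = bound, unbound = unbound))
  }
  # multiframe
  atoms <- .hbond_atoms(on_distance, dha_angle)
  n_on <- round(occupancy * n_frames)
  frames <- lapply(seq_len(n_frames), function(f) {
    shift <- if (f <= n_on) c(0, 0, 0) else c(0, 6, 0)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz[4:6, ] <- sweep(xyz[4:6, , drop = FALSE], 2, shift, `+`)
    xyz
  })
  md_structure(atoms, frames)
}
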