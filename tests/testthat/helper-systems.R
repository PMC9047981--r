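# Shared builders for small test systems.

# two free beads far apart with selected restraints; eps is made tiny so
# the interface term is negligible
two_bead_system <- function(x2 = 30, masses = c(12, 12)) {
  toy_system(positions = rbind(c(0, 0, 0), c(x2, 0, 0)),
             masses = masses, monomer = c("I", "II"),
             epsilon = 1e-9, sigma = 3)
}

# a single harmonic degree of freedom: z of bead 1 under a zfix restraint
one_dof_restraints <- function(k = 50) {
  restraint_set(cv_k = 0, cv_center = 30,
                points = data.frame(bead = 1, type = "zfix", k = k,
                                    y0 = 0, z0 = 0))
}

# random rigid-body transform applied to a structure's coordinates
rigid_transform <- function(structure, seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  shift <- runif(3, -5, 5)
  frames <- lapply(structure$frames, function(f)
    sweep(f %*% t(R), 2, shift, `+`))
  a <- structure$atoms
  a$x <- frames[[1]][, 1]; a$y <- frames[[1]][, 2]; a$z <- frames[[1]][, 3]
  md_structure(a, frames)
}
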