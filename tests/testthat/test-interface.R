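test_that("SASA matches sphere closed forms", {
  # isolated carbon: 4 pi (1.7 + 1.4)^2
  one <- md_structure(data.frame(eleno = 1, name = "CA", resname = "GLY",
                                 chain = "A", resno = 1, insert = "",
                                 element = "C", x = 0, y = 0, z = 0))
  expect_equal(sasa(one)$total, 4 * pi * 3.1^2, tolerance = 1e-9)

  # atom enclosed by an octahedral shell of neighbours: zero area
  oct <- rbind(diag(3), -diag(3))
  shell <- data.frame(eleno = 1:7, name = "CA", resname = "GLY",
                      chain = "A", resno = 1:7, insert = "", element = "C",
                      x = c(0, oct[, 1]), y = c(0, oct[, 2]),
                      z = c(0, oct[, 3]))
  expect_equal(sasa(md_structure(shell))$atom$area[1], 0)

  # two identical spheres: spherical-cap closed form within 2%
  for (d in c(2, 3.5, 5)) {
    two <- data.frame(eleno = 1:2, name = "CA", resname = "GLY",
                      chain = "A", resno = 1:2, insert = "", element = "C",
                      x = c(0, d), y = 0, z = 0)
    res <- sasa(md_structure(two), n_points = 960)
    R <- 3.1
    h <- R - d / 2
    exact <- 4 * pi * R^2 - 2 * pi * R * h
    expect_equal(res$atom$area[1], exact, tolerance = 0.02)
    expect_equal(res$atom$area[2], exact, tolerance = 0.02)
  }
  # unknown element is an explicit error naming the atom
  bad <- data.frame(eleno = 1, name = "XX", resname = "UNK", chain = "A",
                    resno = 1, insert = "", element = "XQ",
                    x = 0, y = 0, z = 0)
  expect_error(sasa(md_structure(bad)), "XQ")
})

test_that("SASA decreases with added neighbours and is additive when separated", {
  fx <- make_structure_fixture("burial")
  sb <- sasa(fx$bound); su <- sasa(fx$unbound)
  # adding neighbours can only bury surface
  expect_lt(sb$total, su$total)
  expect_true(all(sb$residue$area <= su$residue$area + 1e-9))
  # far-separated monomers: total equals the sum of the parts
  a <- fx$unbound$atoms
  ca <- md_structure(a[a$chain == "A", ])
  cb <- md_structure(a[a$chain == "B", ])
  expect_equal(su$total, sasa(ca)$total + sasa(cb)$total, tolerance = 1e-6)
  # per-residue areas sum to the per-atom total
  expect_equal(sum(sb$residue$area), sum(sb$atom$area))
})

test_that("delta-SASA ranks the planted buried residue first", {
  fx <- make_structure_fixture("burial")
  d <- delta_sasa(sasa(fx$bound), sasa(fx$unbound))
  expect_equal(d$chain[1], "A")
  expect_equal(d$resno[1], 2)
  expect_true(all(diff(d$delta_area) <= 1e-9))
  # identical inputs: all zeros
  d0 <- delta_sasa(sasa(fx$bound), sasa(fx$bound))
  expect_equal(max(abs(d0$delta_area)), 0)
  # mismatched residue sets are an alignment error
  expect_error(delta_sasa(sasa(fx$bound), sasa(md_structure(
    fx$unbound$atoms[fx$unbound$atoms$chain == "A", ]))), "alignment")
})

test_that("pi-pi detection follows the printed thresholds strictly", {
  hit <- function(d, a) detect_pipi(make_structure_fixture("pipi",
                                                           distance = d,
                                                           angle = a))
  r <- hit(4.0, 0)
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "pi-pi-parallel")
  expect_equal(r$distance, 4.0, tolerance = 1e-9)
  # beyond the 7.2 A cutoff, and exactly at it: nothing
  expect_equal(nrow(hit(7.5, 0)), 0L)
  expect_equal(nrow(hit(7.2, 0)), 0L)
  # the rejected 30-50 degree band
  expect_equal(nrow(hit(5.0, 40)), 0L)
  expect_equal(nrow(hit(5.0, 31)), 0L)
  expect_equal(nrow(hit(5.0, 49)), 0L)
  # T-shaped above 50 degrees
  rt <- hit(5.0, 70)
  expect_equal(rt$kind, "pi-pi-T-shaped")
  expect_equal(rt$angle, 70, tolerance = 1e-6)
  # parallel below 30
  expect_equal(hit(5.0, 29)$kind, "pi-pi-parallel")
})

test_that("hydrogen-bond detection follows the printed thresholds strictly", {
  hb <- function(d, a) detect_hbonds(make_structure_fixture("hbond",
                                                            on_distance = d,
                                                            dha_angle = a))
  r <- hb(2.8, 160)
  expect_equal(nrow(r), 1L)
  expect_equal(r$distance, 2.8, tolerance = 1e-9)
  expect_equal(r$angle, 160, tolerance = 1e-6)
  # near-collinear bond at 2.8 A fires; 3.2 A does not; 120 deg does not
  expect_equal(nrow(hb(2.8, 179)), 1L)
  expect_equal(nrow(hb(3.2, 179)), 0L)
  expect_equal(nrow(hb(2.8, 120)), 0L)
  # exact boundaries do not fire
  atoms <- data.frame(eleno = 1:3, name = c("N", "H", "O"),
                      resname = "ALA", chain = c("A", "A", "B"),
                      resno = 1, insert = "", element = c("N", "H", "O"),
                      x = c(0, 1.01, 3.0), y = 0, z = 0)
  expect_equal(nrow(detect_hbonds(md_structure(atoms))), 0L)
})

test_that("detectors are invariant under rigid-body motion", {
  fx <- make_structure_fixture("pipi", distance = 5, angle = 20)
  r0 <- detect_pipi(fx)
  r1 <- detect_pipi(rigid_transform(fx, seed = 6))
  expect_equal(r1$distance, r0$distance, tolerance = 1e-9)
  expect_equal(r1$angle, r0$angle, tolerance = 1e-6)

  hb <- make_structure_fixture("hbond", on_distance = 2.7, dha_angle = 155)
  h0 <- detect_hbonds(hb)
  h1 <- detect_hbonds(rigid_transform(hb, seed = 7))
  expect_equal(h1$distance, h0$distance, tolerance = 1e-9)
  expect_equal(h1$angle, h0$angle, tolerance = 1e-6)
})

test_that("occupancy counts detector hits over frames", {
  mf <- make_structure_fixture("multiframe", occupancy = 0.7, n_frames = 10)
  expect_equal(occupancy(mf, detect_hbonds, c("A:1", "B:1")), 70)
  all_on <- make_structure_fixture("multiframe", occupancy = 1, n_frames = 5)
  expect_equal(occupancy(all_on, detect_hbonds, c("A:1", "B:1")), 100)
  none <- make_structure_fixture("multiframe", occupancy = 0, n_frames = 5)
  expect_equal(occupancy(none, detect_hbonds, c("A:1", "B:1")), 0)
  # order of the pair does not matter; frame permutation cannot matter
  expect_equal(occupancy(mf, detect_hbonds, c("B:1", "A:1")), 70)
  perm <- md_structure(mf$atoms, rev(mf$frames))
  expect_equal(occupancy(perm, detect_hbonds, c("A:1", "B:1")), 70)
})

test_that("alanine truncation keeps backbone + CB and renames", {
  fx <- make_structure_fixture("pipi")
  before <- fx$atoms
  mut <- mutate_to_ala(fx, "A", 1)
  kept <- mut$atoms[mut$atoms$chain == "A" & mut$atoms$resno == 1, ]
  expect_true(all(kept$name %in% c("N", "CA", "C", "O", "CB")))
  expect_true(all(kept$resname == "ALA"))
  expect_true("CB" %in% kept$name)
  # the other residue is untouched, bit-identical
  other_before <- before[before$chain == "B", ]
  other_after <- mut$atoms[mut$atoms$chain == "B", ]
  rownames(other_before) <- rownames(other_after) <- NULL
  expect_identical(other_after, other_before)
  # residue count unchanged
  nres <- function(s) length(unique(paste(s$atoms$chain, s$atoms$resno)))
  expect_equal(nres(mut), nres(fx))
  # idempotent: mutating again changes nothing
  expect_identical(mutate_to_ala(mut, "A", 1)$atoms, mut$atoms)
  # atom count: PHE (ring 6 + CB + CA + N + C + O = 11) -> backbone 4 + CB
  expect_equal(nrow(kept), 5L)
  # glycine and missing residues are explicit errors
  g <- md_structure(data.frame(eleno = 1:2, name = c("N", "CA"),
                               resname = "GLY", chain = "A", resno = 1,
                               insert = "", element = c("N", "C"),
                               x = 0:1, y = 0, z = 0))
  expect_error(mutate_to_ala(g, "A", 1), "glycine")
  expect_error(mutate_to_ala(fx, "Z", 99), "lookup error")
})

test_that("the nonpolar solvation term is the linear SASA model", {
  expect_equal(nonpolar_solvation(0), 0)
  expect_equal(nonpolar_solvation(1000), 7.2)
  # additive over disjoint groups
  expect_equal(nonpolar_solvation(300) + nonpolar_solvation(700),
               nonpolar_solvation(1000))
  expect_error(nonpolar_solvation(-1), "domain error")
})
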