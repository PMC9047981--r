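# Geometric interaction detectors. Thresholds are strict inequalities:
# pi-pi fires below 7.2 A ring-centre distance with normal-normal acute
# angle below 30 deg (parallel) or above 50 deg (T-shaped); hydrogen
# bonds fire below 3.0 A O-N distance with donor-H-acceptor angle above
# 135 deg. Boundary values do not fire.

.PIPI_DIST <- 7.2
.PIPI_PAR <- 30
.PIPI_TSH <- 50
.HB_DIST <- 3.0
.HB_ANGLE <- 135

# six-membered aromatic ring atoms of the residues the detector knows
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
)

# default monomer assignment: every chain its own monomer
.monomer_map <- function(structure, monomers) {
  chains <- unique(structure$atoms$chain)
  if (is.null(monomers)) {
    mm <- stats::setNames(chains, chains)
  } else {
    mm <- stats::setNames(rep(names(monomers), lengths(monomers)),
                          unlist(monomers))
  }
  miss <- setdiff(chains, names(mm))
  if (length(miss))
    stop("monomer assignment missing for chain(s): ",
         paste(miss, collapse = ", "))
  mm
}

# best-fit ring normal: singular vector of the smallest singular value
.ring_normal <- function(xyz) {
  c0 <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, c0))
  list(center = c0, normal = sv$v[, 3])
}

.acute_angle_deg <- function(n1, n2) {
  ca <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, ca)) * 180 / pi
}

#' Detect pi-pi interactions between monomers
#'
#' Every inter-monomer pair of aromatic six-rings (Phe/Tyr by default)
#' whose ring-centre distance is below 7.2 A is classified by the
#' acute angle between best-fit ring normals: below 30 deg parallel,
#' above 50 deg T-shaped; the 30-50 deg band is rejected.
#'
#' @param structure An [md_structure()].
#' @param ring_definitions Named list mapping residue names to their
#'   ring atom names; defaults to the Phe/Tyr six-ring.
#' @param monomers Named list mapping monomer ids to chain vectors,
#'   e.g. `list(I = c("A","B"), II = c("C","D"))`. Default: each chain
#'   is its own monomer.
#' @param frame Frame to analyse.
#' @return Data frame of interaction records: `kind`
#'   (`pi-pi-parallel` / `pi-pi-T-shaped`), residue identifiers,
#'   `distance` (A), `angle` (deg), `frame`.
#' @export
detect_pipi <- function(structure, ring_definitions = NULL,
                        monomers = NULL, frame = 1L) {
  if (is.null(ring_definitions)) ring_definitions <- .RING_ATOMS
  a <- structure$atoms
  xyz <- frame_coords(structure, frame)
  mm <- .monomer_map(structure, monomers)
  rkey <- paste(a$chain, a$resno, a$insert, sep = ":")
  rings <- list()
  for (key in unique(rkey)) {
    idx <- which(rkey == key)
    rn <- a$resname[idx[1]]
    if (!rn %in% names(ring_definitions)) next
    ridx <- idx[a$name[idx] %in% ring_definitions[[rn]]]
    if (length(ridx) < 3)
      stop(sprintf("geometry error: ring of %s %s has fewer than 3 atoms",
                   rn, key))
    rings[[key]] <- c(.ring_normal(xyz[ridx, , drop = FALSE]),
                      list(chain = a$chain[idx[1]], resno = a$resno[idx[1]],
                           resname = rn))
  }
  out <- list()
  keys <- names(rings)
  if (length(keys) >= 2) {
    for (i in seq_len(length(keys) - 1)) for (j in (i + 1):length(keys)) {
      r1 <- rings[[keys[i]]]; r2 <- rings[[keys[j]]]
      if (mm[r1$chain] == mm[r2$chain]) next
      d <- sqrt(sum((r1$center - r2$center)^2))
      if (d >= .PIPI_DIST) next
      ang <- .acute_angle_deg(r1$normal, r2$normal)
      kind <- if (ang < .PIPI_PAR) "pi-pi-parallel"
      else if (ang > .PIPI_TSH) "pi-pi-T-shaped"
      else next
      out[[length(out) + 1]] <- data.frame(
        kind = kind, chain1 = r1$chain, resno1 = r1$resno,
        resname1 = r1$resname, chain2 = r2$chain, resno2 = r2$resno,
        resname2 = r2$resname, distance = d, angle = ang, frame = frame,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(kind = character(), chain1 = character(),
                      resno1 = integer(), resname1 = character(),
                      chain2 = character(), resno2 = integer(),
                      resname2 = character(), distance = numeric(),
                      angle = numeric(), frame = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# donor nitrogen names per residue (backbone N always a donor)
.SIDECHAIN_DONOR_N <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  HID = "ND1", HIE = "NE2", TRP = "NE1", ASN = "ND2", GLN = "NE2"
)

# ideal backbone amide H: along the negative bisector of N->CA and
# N->C(previous residue); used when the file carries no hydrogens
.ideal_backbone_h <- function(a, xyz, i_n) {
  ch <- a$chain[i_n]; rn <- a$resno[i_n]
  i_ca <- which(a$chain == ch & a$resno == rn & a$name == "CA")
  i_cp <- which(a$chain == ch & a$resno == rn - 1 & a$name == "C")
  if (!length(i_ca) || !length(i_cp)) return(NULL)
  u1 <- xyz[i_ca[1], ] - xyz[i_n, ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- xyz[i_cp[1], ] - xyz[i_n, ]; u2 <- u2 / sqrt(sum(u2^2))
  d <- -(u1 + u2); d <- d / sqrt(sum(d^2))
  xyz[i_n, ] + 1.01 * d
}

#' Detect inter-monomer hydrogen bonds
#'
#' Every inter-monomer donor-nitrogen / acceptor-oxygen pair with O-N
#' distance below 3.0 A and donor-H-acceptor angle above 135 deg.
#' Donor hydrogens are taken from the file (any H within 1.25 A of the
#' donor N); for backbone nitrogens without hydrogens an ideal amide H
#' is placed along the bisector geometry and the placement is counted
#' in the `n_ideal_h` attribute. Donors with no resolvable hydrogen are
#' skipped with a warning (`n_skipped` attribute).
#'
#' @inheritParams detect_pipi
#' @return Data frame of `hbond` records with `distance` (O-N, A) and
#'   `angle` (donor-H-acceptor, deg).
#' @export
detect_hbonds <- function(structure, monomers = NULL, frame = 1L) {
  a <- structure$atoms
  xyz <- frame_coords(structure, frame)
  mm <- .monomer_map(structure, monomers)
  donors <- which(a$element == "N" &
                    (a$name == "N" |
                       mapply(function(rn, nm)
                         nm %in% (.SIDECHAIN_DONOR_N[[rn]] %||% character()),
                         a$resname, a$name)))
  acceptors <- which(a$element == "O")
  hyd <- which(a$element == "H")
  out <- list(); n_skipped <- 0L; n_ideal <- 0L
  for (d in donors) {
    hs <- hyd[a$chain[hyd] == a$chain[d] & a$resno[hyd] == a$resno[d]]
    if (length(hs)) {
      dh <- sqrt(rowSums((xyz[hs, , drop = FALSE] -
                            matrix(xyz[d, ], length(hs), 3, byrow = TRUE))^2))
      hs <- hs[dh < 1.25]
    }
    hpos <- if (length(hs)) xyz[hs, , drop = FALSE] else NULL
    if (is.null(hpos) && a$name[d] == "N") {
      ideal <- .ideal_backbone_h(a, xyz, d)
      if (!is.null(ideal)) {
        hpos <- matrix(ideal, 1, 3)
        n_ideal <- n_ideal + 1L
      }
    }
    if (is.null(hpos)) {
      n_skipped <- n_skipped + 1L
      next
    }
    for (acc in acceptors) {
      if (mm[a$chain[acc]] == mm[a$chain[d]]) next
      don <- sqrt(sum((xyz[acc, ] - xyz[d, ])^2))
      if (don >= .HB_DIST) next
      ang <- max(apply(hpos, 1, function(h) {
        v1 <- xyz[d, ] - h; v2 <- xyz[acc, ] - h
        acos(min(1, max(-1, sum(v1 * v2) /
                          sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }))
      if (ang <= .HB_ANGLE) next
      out[[length(out) + 1]] <- data.frame(
        kind = "hbond", chain1 = a$chain[d], resno1 = a$resno[d],
        resname1 = a$resname[d], atom1 = a$name[d],
        chain2 = a$chain[acc], resno2 = a$resno[acc],
        resname2 = a$resname[acc], atom2 = a$name[acc],
        distance = don, angle = ang, frame = frame,
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0)
    warning(sprintf("%d donor nitrogen(s) without resolvable hydrogens skipped",
                    n_skipped))
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), chain1 = character(), resno1 = integer(),
               resname1 = character(), atom1 = character(),
               chain2 = character(), resno2 = integer(),
               resname2 = character(), atom2 = character(),
               distance = numeric(), angle = numeric(), frame = integer(),
               stringsAsFactors = FALSE)
  attr(res, "n_skipped") <- n_skipped
  attr(res, "n_ideal_h") <- n_ideal
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-frame occupancy of an interaction pair
#'
#' Percentage of frames in which a detector reports an interaction
#' between the given residue pair (order-insensitive).
#'
#' @param frames A multi-frame [md_structure()].
#' @param detector A detector function such as [detect_hbonds()] or
#'   [detect_pipi()], called per frame.
#' @param pair Character vector of two residue ids `"chain:resno"`.
#' @param ... Passed on to the detector.
#' @return Occupancy in percent (0-100).
#' @export
occupancy <- function(frames, detector, pair, ...) {
  nf <- n_frames(frames)
  stopifnot(nf >= 1L, length(pair) == 2L)
  hits <- 0L
  for (f in seq_len(nf)) {
    rec <- suppressWarnings(detector(frames, frame = f, ...))
    if (!nrow(rec)) next
    id1 <- paste(rec$chain1, rec$resno1, sep = ":")
    id2 <- paste(rec$chain2, rec$resno2, sep = ":")
    if (any((id1 == pair[1] & id2 == pair[2]) |
            (id1 == pair[2] & id2 == pair[1])))
      hits <- hits + 1L
  }
  100 * hits / nf
}
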