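# Solvent-accessible surface area by Shrake-Rupley sphere sampling:
# quasi-uniform test points on each atom's solvent-extended sphere
# (vdW radius + probe), a point is accessible if it lies outside every
# neighbour's extended sphere.

# quasi-uniform points on the unit sphere (golden-spiral / Fibonacci)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Per-atom, per-residue and total SASA of one frame, using Bondi van
#' der Waals radii (see [vdw_radii()]) and a rolling probe.
#'
#' @param structure An [md_structure()].
#' @param probe Probe radius (Angstrom); 1.4 approximates water.
#' @param n_points Sphere quadrature points per atom.
#' @param frame Frame index to evaluate.
#' @return An object of class `sasa_result`: list with `atom` (data
#'   frame incl. `area`), `residue` (per-residue totals), `total`,
#'   `probe`, `n_points`.
#' @examples
#' s <- make_structure_fixture("hbond")
#' sasa(s)$total
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, frame = 1L) {
  a <- structure$atoms
  xyz <- frame_coords(structure, frame)
  radii <- vdw_radii()
  unknown <- !(a$element %in% names(radii))
  if (any(unknown)) {
    bad <- which(unknown)[1]
    stop(sprintf(
      "no van der Waals radius for element '%s' (atom %d %s %s%d %s)",
      a$element[bad], a$eleno[bad], a$name[bad], a$chain[bad],
      a$resno[bad], a$resname[bad]))
  }
  r_ext <- radii[a$element] + probe
  n <- nrow(a)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    ri <- r_ext[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + r_ext)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * ri^2
      next
    }
    tp <- pts * ri
    tp <- sweep(tp, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    # check nearest neighbours first: most points die early
    for (j in nb[order(d2[nb])]) {
      if (!any(acc)) break
      dd <- (tp[acc, 1] - xyz[j, 1])^2 + (tp[acc, 2] - xyz[j, 2])^2 +
        (tp[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dd >= r_ext[j]^2
    }
    area[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  atom <- cbind(a, area = area)
  res_key <- paste(a$chain, a$resno, a$insert, sep = ":")
  agg <- stats::aggregate(area, by = list(key = res_key), FUN = sum)
  first <- !duplicated(res_key)
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resname = a$resname[first],
                    key = res_key[first], stringsAsFactors = FALSE)
  res$area <- agg$x[match(res$key, agg$key)]
  res$key <- NULL
  structure(list(atom = atom, residue = res, total = sum(area),
                 probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 over %d atoms / %d residues (probe %.2f A, %d points)\n",
              x$total, nrow(x$atom), nrow(x$residue), x$probe, x$n_points))
  invisible(x)
}

#' Ranked per-residue SASA differences (burial on binding)
#'
#' For each residue, `unbound - bound` SASA, sorted descending so the
#' residues most buried by complex formation rank first; ties broken by
#' residue number.
#'
#' @param bound,unbound [sasa()] results over the same residue set.
#' @return Data frame with `chain`, `resno`, `resname`, `delta_area`
#'   (A^2), sorted.
#' @export
delta_sasa <- function(bound, unbound) {
  kb <- paste(bound$residue$chain, bound$residue$resno, bound$residue$insert)
  ku <- paste(unbound$residue$chain, unbound$residue$resno,
              unbound$residue$insert)
  if (length(kb) != length(ku) || !setequal(kb, ku))
    stop("alignment error: bound and unbound residue sets differ")
  m <- match(kb, ku)
  d <- data.frame(chain = bound$residue$chain, resno = bound$residue$resno,
                  resname = bound$residue$resname,
                  delta_area = unbound$residue$area[m] - bound$residue$area,
                  stringsAsFactors = FALSE)
  d[order(-d$delta_area, d$resno), , drop = FALSE]
}

#' Nonpolar solvation free energy from SASA
#'
#' The linear surface-area model `G = 0.0072 * SASA` (SASA in A^2,
#' result in kcal/mol).
#'
#' @param total_sasa Total SASA (A^2), >= 0.
#' @return Nonpolar solvation free energy (kcal/mol).
#' @examples
#' nonpolar_solvation(1000) # 7.2
#' @export
nonpolar_solvation <- function(total_sasa) {
  if (any(!is.finite(total_sasa)) || any(total_sasa < 0))
    stop("domain error: SASA must be >= 0")
  0.0072 * total_sasa
}
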