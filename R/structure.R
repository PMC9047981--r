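#' Molecular structure container
#'
#' Atoms plus one coordinate set per model (frame). Single-model
#' structures have one frame; trajectories read from multi-model PDB
#' files keep every frame.
#'
#' @param atoms Data frame with columns `eleno`, `name`, `resname`,
#'   `chain`, `resno`, `insert`, `element`, `x`, `y`, `z`.
#' @param frames List of n x 3 coordinate matrices; defaults to one
#'   frame taken from the atom table.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, frames = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("eleno", "name", "resname", "chain", "resno", "insert",
            "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("invalid structure: missing atom columns ", paste(miss, collapse = ", "))
  if (is.null(frames)) frames <- list(as.matrix(atoms[, c("x", "y", "z")]))
  for (f in frames) {
    if (!all(dim(as.matrix(f)) == c(nrow(atoms), 3)) || any(!is.finite(f)))
      stop("invalid structure: frames must be finite n x 3 matrices")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key))
    stop("invalid structure: duplicated (chain, residue, atom name)")
  structure(list(atoms = atoms, frames = lapply(frames, function(f) {
    f <- as.matrix(f); dimnames(f) <- NULL; f
  })), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(x$frames), "frame(s),",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Number of frames (models) in a structure
#' @param structure An [md_structure()].
#' @return Integer.
#' @export
n_frames <- function(structure) length(structure$frames)

#' Coordinates of one frame
#' @param structure An [md_structure()].
#' @param frame Frame index.
#' @return n x 3 matrix.
#' @export
frame_coords <- function(structure, frame = 1L) {
  if (frame < 1L || frame > length(structure$frames))
    stop("frame index out of range")
  structure$frames[[frame]]
}

# single-frame copy with coordinates from the given frame
.at_frame <- function(structure, frame) {
  xyz <- frame_coords(structure, frame)
  a <- structure$atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  md_structure(a)
}

.validate_pdb_lines <- function(lines) {
  rec <- substring(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("PDB parse error at line %d: record shorter than 54 columns", i))
    coords <- suppressWarnings(as.numeric(c(substring(ln, 31, 38),
                                            substring(ln, 39, 46),
                                            substring(ln, 47, 54))))
    if (any(is.na(coords)))
      stop(sprintf("PDB parse error at line %d: non-numeric coordinate field", i))
  }
  invisible(TRUE)
}

.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substring(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "SE", "ZN", "MG", "FE", "NA", "MN"),
         two, substring(nm, 1, 1))
}

#' Read a PDB file or text
#'
#' Fixed-column PDB parsing (via bio3d) with a validation pass that
#' reports malformed ATOM/HETATM records by line number. Multi-model
#' files become multi-frame structures; insertion codes are preserved.
#'
#' @param input A file path, or PDB text (single string or character
#'   vector of lines).
#' @return An [md_structure()].
#' @export
read_pdb <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  .validate_pdb_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)
  a <- p$atom
  elem <- toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                         .element_from_name(a$elety), a$elesy))
  atoms <- data.frame(
    eleno = a$eleno, name = a$elety, resname = a$resid,
    chain = ifelse(is.na(a$chain), " ", a$chain), resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    element = trimws(elem),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  )
  nm <- nrow(p$xyz)
  frames <- lapply(seq_len(max(1L, nm)), function(i)
    matrix(p$xyz[i, ], ncol = 3, byrow = TRUE))
  md_structure(atoms, frames)
}

.fmt_atom_name <- function(name, element) {
  # names occupy cols 13-16; 1-letter elements start at col 14
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(element) == 2, sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write a structure as PDB text
#'
#' Multi-frame structures are written as multi-model files
#' (MODEL/ENDMDL). Coordinates are written at 1e-3 Angstrom precision,
#' the PDB fixed-column standard.
#'
#' @param structure An [md_structure()].
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The PDB lines, invisibly when `path` is given.
#' @export
write_pdb <- function(structure, path = NULL) {
  a <- structure$atoms
  nmname <- .fmt_atom_name(a$name, a$element)
  one_model <- function(xyz) {
    sprintf("ATOM  %5d %s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$eleno, nmname, substr(a$resname, 1, 3), a$chain, a$resno,
            ifelse(a$insert == "", " ", a$insert),
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
  }
  nf <- length(structure$frames)
  if (nf == 1L) {
    out <- c(one_model(structure$frames[[1]]), "END")
  } else {
    out <- unlist(lapply(seq_len(nf), function(i)
      c(sprintf("MODEL     %4d", i), one_model(structure$frames[[i]]),
        "ENDMDL")))
    out <- c(out, "END")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Convert toy-simulation frames to a structure
#'
#' Beads become carbon pseudo-atoms (residue `BEA`), chain A for monomer
#' I and chain B for monomer II, so toy trajectories can be written as
#' multi-model PDB and fed to the structural analyzers.
#'
#' @param frames List of n x 3 coordinate matrices (e.g. `$frames` from
#'   [run_equilibrium()]).
#' @param system The [toy_system()] the frames belong to.
#' @return An [md_structure()].
#' @export
toy_frames_to_structure <- function(frames, system) {
  n <- nrow(system$positions)
  atoms <- data.frame(
    eleno = seq_len(n), name = "CA", resname = "BEA",
    chain = ifelse(system$monomer == "I", "A", "B"),
    resno = seq_len(n), insert = "", element = "C",
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    stringsAsFactors = FALSE
  )
  md_structure(atoms, frames)
}
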