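# Alanine truncation: remove all sidechain atoms beyond C-beta and
# rename the residue ALA. Backbone atoms (and backbone hydrogens) are
# untouched; missing hydrogens are left for downstream tooling to add.

.ALA_KEEP <- c("N", "CA", "C", "O", "OXT", "CB",
               "H", "H1", "H2", "H3", "HA", "HXT")

#' Truncate a residue to alanine
#'
#' Keeps the backbone plus the C-beta atom of the selected residue and
#' renames it `ALA`; every other residue is untouched. A residue that
#' is already alanine is returned unchanged (idempotent). Glycine has
#' no C-beta and is rejected.
#'
#' @param structure An [md_structure()].
#' @param chain Chain identifier.
#' @param residue_number Residue number within the chain.
#' @return The mutated [md_structure()].
#' @examples
#' s <- make_structure_fixture("pipi")
#' mutate_to_ala(s, "A", 1)
#' @export
mutate_to_ala <- function(structure, chain, residue_number) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == residue_number
  if (!any(sel))
    stop(sprintf("lookup error: no residue %s%d in structure",
                 chain, residue_number))
  rn <- unique(a$resname[sel])
  if (identical(rn, "GLY"))
    stop("no-C-beta error: glycine cannot be truncated to alanine")
  if (identical(rn, "ALA")) return(structure)
  if (!any(a$name[sel] == "CB"))
    stop(sprintf("no-C-beta error: residue %s %s%d has no CB atom",
                 rn, chain, residue_number))
  drop <- sel & !(a$name %in% .ALA_KEEP)
  keep <- !drop
  a2 <- a[keep, , drop = FALSE]
  a2$resname[a2$chain == chain & a2$resno == residue_number] <- "ALA"
  frames <- lapply(structure$frames, function(f) f[keep, , drop = FALSE])
  md_structure(a2, frames)
}
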