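#' Amino-acid alphabet and physicochemical groups
#'
#' Constants shared across the package: the 20 standard amino acids
#' (three-letter codes, alphabetical), the mapping of common
#' non-standard residues to their standard parents, and the seven
#' physicochemical groups used for group potentials.
#'
#' @name mempot-alphabet
#' @keywords internal
NULL

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")

#  modified residues mapped to their standard parent; anything else
#  among HETATM records is skipped
NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", MLY = "LYS", CSO = "CYS",
                     PTR = "TYR", SEP = "SER", TPO = "THR", HYP = "PRO")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

aa_index <- function(aa) {
  i <- match(toupper(aa), AA3)
  if (anyNA(i)) stop("unknown amino-acid type(s): ",
                     paste(unique(aa[is.na(i)]), collapse = ", "))
  i
}

#' Define an amino-acid group for group potentials
#'
#' A group pools amino acids with similar physicochemistry.  When
#' counting pairs, inter-residue distances involving larger members are
#' shifted towards smaller values by the difference between the
#' member's side-chain radius and the radius of the smallest member, so
#' that the pooled distance axis is comparable across members.
#'
#' @param name group name.
#' @param members character vector of three-letter amino-acid codes.
#' @param radii named numeric vector or [estimate_residue_radii()]
#'   result giving side-chain radii in Angstrom for at least the
#'   members.
#' @return an object of class `group_def` with fields `name`,
#'   `members` and per-member shifts `delta` (Angstrom, >= 0, zero for
#'   the smallest member).
#' @export
group_def <- function(name, members, radii) {
  members <- toupper(members)
  aa_index(members)                      # validates
  r <- radii[members]
  if (anyNA(r)) stop("group member without a radius: ",
                     paste(members[is.na(r)], collapse = ", "))
  delta <- as.numeric(r - min(r))
  names(delta) <- members
  structure(list(name = name, members = members, delta = delta),
            class = "group_def")
}

#' Standard amino-acid groups
#'
#' The seven groups used throughout: positively charged (Lys, Arg),
#' negatively charged (Glu, Asp), aromatic (Phe, Tyr, Trp), aliphatic
#' (Ile, Val, Leu), non-charged polar (Gln, Asn, Ser, Thr), small
#' (Gly, Ala) and sulfur-containing (Cys, Met).  His and Pro belong to
#' no group.
#'
#' @param radii named radii vector (see [group_def()]); defaults to
#'   [default_residue_radii()].
#' @return named list of `group_def` objects.
#' @export
standard_groups <- function(radii = default_residue_radii()) {
  defs <- list(
    positive  = c("LYS", "ARG"),
    negative  = c("GLU", "ASP"),
    aromatic  = c("PHE", "TYR", "TRP"),
    aliphatic = c("ILE", "VAL", "LEU"),
    polar     = c("GLN", "ASN", "SER", "THR"),
    small     = c("GLY", "ALA"),
    sulfur    = c("CYS", "MET"))
  out <- lapply(names(defs), function(nm) group_def(nm, defs[[nm]], radii))
  names(out) <- names(defs)
  out
}

#' Default side-chain radius table
#'
#' Mean distance of side-chain heavy atoms to the side-chain geometric
#' center, in Angstrom, computed once from the package's full-atom
#' synthetic structure library (see `estimate_residue_radii()`).  Gly
#' is 0 by convention (its "side chain" is the C-alpha atom) and Ala is
#' 0 because a single C-beta atom coincides with its own centroid.
#'
#' @return named numeric vector over the 20 amino acids.
#' @export
default_residue_radii <- function() {
  if (is.null(.radius_cache$r)) {
    tpls <- sidechain_templates()
    .radius_cache$r <- vapply(AA3, function(aa) template_radius(tpls[[aa]]),
                              numeric(1))
  }
  .radius_cache$r
}

.radius_cache <- new.env(parent = emptyenv())
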