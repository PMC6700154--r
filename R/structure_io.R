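#' Parse a protein structure into a labeled residue list
#'
#' Reads a PDB file (or raw PDB text) with \pkg{bio3d}, keeps the
#' standard amino-acid residues (mapping selenomethionine and a few
#' other common modified residues to their standard parents), resolves
#' alternate locations to the highest-occupancy conformer (ties broken
#' towards altLoc 'A'), collapses insertion codes into a consecutive
#' per-chain residue index, and computes the side-chain geometric
#' center of every residue.
#'
#' All regions start `UNASSIGNED`; see [assign_regions()].
#'
#' @param input path to a PDB file, or a character vector of PDB text
#'   lines (a single string with embedded newlines also works).
#' @param id structure identifier stored in the result; defaults to
#'   the file base name.
#' @param topology_class one of `"alpha_helical"`, `"beta_barrel"`,
#'   `"monotopic"`, `"unknown"`.
#' @param keep_atoms if `TRUE`, the per-atom table (needed by
#'   [estimate_residue_radii()]) is retained in the result.
#' @return an object of class `labeled_structure`: a list with
#'   `structure_id`, `topology_class`, `residues` (data frame with
#'   columns chain, seq_index, resno, aa, x, y, z, region, side,
#'   center_fallback) and optionally `atoms`.
#' @export
parse_structure <- function(input, id = NULL, topology_class = "unknown",
                            keep_atoms = FALSE) {
  if (length(input) > 1L || grepl("\n", input[1], fixed = TRUE) ||
      !file.exists(input[1])) {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(id)) id <- "structure"
  } else {
    path <- input
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB input: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at$resid <- toupper(at$resid)
  mapped <- !is.na(match(at$resid, names(NONSTANDARD_MAP)))
  at$resid[mapped] <- NONSTANDARD_MAP[at$resid[mapped]]
  at <- at[at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0L) stop("structure contains no standard amino-acid residues")
  # drop hydrogens/deuteriums
  elty <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substring(gsub("^[0-9]", "", at$elety), 1, 1),
                         at$elesy))
  at <- at[!elty %in% c("H", "D"), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  rk <- paste(at$chain, at$resno, at$insert, sep = "|")
  at <- resolve_altloc(at, rk)
  rk <- paste(at$chain, at$resno, at$insert, sep = "|")

  ord <- order(match(at$chain, unique(at$chain)), at$resno,
               match(at$insert, c("", LETTERS)))
  at <- at[ord, , drop = FALSE]
  rk <- rk[ord]
  ukeys <- unique(rk)
  first <- match(ukeys, rk)

  res <- data.frame(chain = at$chain[first],
                    resno = at$resno[first],
                    aa = at$resid[first],
                    stringsAsFactors = FALSE)
  centers <- matrix(NA_real_, nrow(res), 3)
  fallback <- logical(nrow(res))
  for (k in seq_along(ukeys)) {
    sel <- which(rk == ukeys[k])
    ctr <- compute_side_chain_center(
      data.frame(atom = at$elety[sel], x = at$x[sel], y = at$y[sel],
                 z = at$z[sel], stringsAsFactors = FALSE),
      aa = res$aa[k])
    centers[k, ] <- ctr
    fallback[k] <- isTRUE(attr(ctr, "fallback"))
  }
  keep <- is.finite(centers[, 1])
  if (any(!keep))
    warning(sum(!keep), " residue(s) dropped: no resolvable heavy atoms")
  res <- res[keep, , drop = FALSE]
  centers <- centers[keep, , drop = FALSE]
  fallback <- fallback[keep]
  if (nrow(res) == 0L) stop("structure contains no resolvable residues")

  seq_index <- stats::ave(seq_len(nrow(res)), res$chain,
                          FUN = seq_along)
  residues <- data.frame(chain = res$chain, seq_index = seq_index,
                         resno = res$resno, aa = res$aa,
                         x = centers[, 1], y = centers[, 2], z = centers[, 3],
                         region = "UNASSIGNED", side = NA_character_,
                         center_fallback = fallback,
                         stringsAsFactors = FALSE)
  out <- list(structure_id = id, topology_class = topology_class,
              residues = residues)
  if (keep_atoms) {
    ridx <- match(rk, ukeys)
    kidx <- match(ridx, which(keep))
    akeep <- !is.na(kidx)
    out$atoms <- data.frame(chain = at$chain[akeep],
                            seq_index = seq_index[kidx[akeep]],
                            resno = at$resno[akeep],
                            aa = at$resid[akeep],
                            atom = at$elety[akeep],
                            x = at$x[akeep], y = at$y[akeep], z = at$z[akeep],
                            stringsAsFactors = FALSE)
  }
  structure(out, class = "labeled_structure")
}

# keep, per atom name within a residue, the conformer with the highest
# occupancy; ties go to the alphabetically first altLoc
resolve_altloc <- function(at, rk) {
  if (all(at$alt == "")) return(at)
  key <- paste(rk, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

#' Side-chain geometric center of one residue
#'
#' Unweighted mean of the side-chain heavy-atom coordinates (C-beta
#' and beyond; hydrogens are assumed already excluded).  Gly returns
#' its C-alpha.  A residue whose side-chain atoms are all missing
#' falls back to C-alpha and is flagged via the `"fallback"`
#' attribute.
#'
#' @param residue_atoms data frame with columns `atom`, `x`, `y`, `z`.
#' @param aa three-letter residue type (controls the Gly convention).
#' @return numeric length-3 coordinate (Angstrom); `NA`s if no heavy
#'   atom is usable.
#' @export
compute_side_chain_center <- function(residue_atoms, aa = NULL) {
  if (nrow(residue_atoms) == 0L) stop("residue has no heavy atoms")
  an <- toupper(residue_atoms$atom)
  xyz <- as.matrix(residue_atoms[, c("x", "y", "z")])
  ca <- which(an == "CA")
  if (!is.null(aa) && toupper(aa) == "GLY") {
    if (length(ca)) return(as.numeric(xyz[ca[1], ]))
    return(structure(as.numeric(colMeans(xyz)), fallback = TRUE))
  }
  sc <- which(!an %in% BACKBONE_ATOMS)
  if (length(sc))
    return(as.numeric(colMeans(xyz[sc, , drop = FALSE])))
  if (length(ca))
    return(structure(as.numeric(xyz[ca[1], ]), fallback = TRUE))
  structure(as.numeric(colMeans(xyz)), fallback = TRUE)
}

#' Read a region-annotation table
#'
#' Tab-separated file with header
#' `structure_id  chain  start  end  region  side`; `start`/`end` are
#' 1-based inclusive residue ranges in author numbering, `region` is
#' `TM` or `EM`, `side` is `in`, `out` or `-`.
#'
#' @param path file path.
#' @return data frame of annotation records (class `region_annotation`).
#' @export
read_region_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "integer",
                                          "character", "character"))
  names(ann) <- c("structure_id", "chain", "start", "end", "region", "side")
  validate_annotation(ann)
}

#' Build an annotation table in code
#' @param structure_id,chain,start,end,region,side vectors, recycled
#'   to a common length.
#' @return data frame of class `region_annotation`.
#' @export
region_annotation <- function(structure_id, chain, start, end, region,
                              side = "-") {
  ann <- data.frame(structure_id = structure_id, chain = chain,
                    start = as.integer(start), end = as.integer(end),
                    region = region, side = side,
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  stopifnot(all(ann$region %in% c("TM", "EM")),
            all(ann$start <= ann$end))
  sp <- split(ann, paste(ann$structure_id, ann$chain))
  for (seg in sp) {
    seg <- seg[order(seg$start), ]
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("overlapping annotation segments in structure ",
           seg$structure_id[1], " chain ", seg$chain[1])
  }
  class(ann) <- c("region_annotation", "data.frame")
  ann
}

#' Assign TM/EM region labels to a parsed structure
#'
#' Residues whose author residue number falls inside an annotated
#' segment of their chain take that segment's region (and side label).
#' Residues not covered by any segment default to `EM`: membrane
#' proteins are annotated by their membrane-embedded segments, so the
#' unannotated remainder is extramembrane by construction.  With
#' `strict = TRUE` an empty annotation for the structure is an error
#' instead.
#'
#' @param structure a `labeled_structure`.
#' @param annotation a `region_annotation` table.
#' @param strict error when no annotation records exist for this
#'   structure.
#' @return the structure with regions resolved.
#' @export
assign_regions <- function(structure, annotation, strict = FALSE) {
  stopifnot(inherits(structure, "labeled_structure"))
  ann <- annotation[annotation$structure_id == structure$structure_id, ,
                    drop = FALSE]
  if (nrow(ann) == 0L) {
    if (strict) stop("no annotation records for structure ",
                     structure$structure_id)
    structure$residues$region <- "EM"
    return(structure)
  }
  missing_chain <- setdiff(ann$chain, unique(structure$residues$chain))
  if (length(missing_chain))
    stop("annotation references missing chain(s): ",
         paste(missing_chain, collapse = ", "))
  res <- structure$residues
  res$region <- "EM"
  res$side <- NA_character_
  for (k in seq_len(nrow(ann))) {
    hit <- res$chain == ann$chain[k] &
      res$resno >= ann$start[k] & res$resno <= ann$end[k]
    res$region[hit] <- ann$region[k]
    if (!is.na(ann$side[k]) && ann$side[k] %in% c("in", "out"))
      res$side[hit] <- ann$side[k]
  }
  structure$residues <- res
  structure
}

#' Estimate side-chain radii from full-atom structures
#'
#' For each amino-acid type, the radius is the mean over all its
#' occurrences of the mean distance of the side-chain heavy atoms to
#' the side-chain geometric center.  Gly is 0 by convention.  Types
#' absent from the input fall back to [default_residue_radii()].
#'
#' @param structures list of `labeled_structure` objects parsed with
#'   `keep_atoms = TRUE`.
#' @return named numeric vector over the 20 amino acids (Angstrom).
#' @export
estimate_residue_radii <- function(structures) {
  if (length(structures) == 0L) stop("empty structure list")
  acc <- stats::setNames(numeric(20), AA3)
  cnt <- stats::setNames(integer(20), AA3)
  for (s in structures) {
    if (is.null(s$atoms)) stop("structure ", s$structure_id,
                               " lacks atom detail (parse with keep_atoms = TRUE)")
    at <- s$atoms
    sc <- at[!toupper(at$atom) %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(sc) == 0L) next
    key <- paste(sc$chain, sc$seq_index)
    for (sel in split(seq_len(nrow(sc)), key)) {
      aa <- sc$aa[sel[1]]
      if (aa == "GLY") next
      xyz <- as.matrix(sc[sel, c("x", "y", "z")])
      ctr <- colMeans(xyz)
      acc[aa] <- acc[aa] + mean(sqrt(rowSums(sweep(xyz, 2, ctr)^2)))
      cnt[aa] <- cnt[aa] + 1L
    }
  }
  out <- default_residue_radii()
  seen <- cnt > 0L
  out[names(acc)[seen]] <- acc[seen] / cnt[seen]
  out["GLY"] <- 0
  out
}

#' Write a labeled structure back to PDB text
#'
#' Emits one C-alpha record and one side-chain-center pseudo-atom
#' (written as C-beta; Gly gets only C-alpha at its center) per
#' residue, so that re-parsing reproduces the side-chain centers.
#'
#' @param structure a `labeled_structure`.
#' @param path output path; if `NULL` the PDB text lines are returned.
#' @return invisibly, the PDB text lines.
#' @export
write_structure_pdb <- function(structure, path = NULL) {
  res <- structure$residues
  lines <- character(0)
  serial <- 0L
  fmt <- function(serial, name, aa, chain, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, paste0(" ", name), aa, chain, resno, x, y, z,
            substring(name, 1, 1))
  for (i in seq_len(nrow(res))) {
    serial <- serial + 1L
    if (res$aa[i] == "GLY") {
      lines <- c(lines, fmt(serial, "CA", res$aa[i], res$chain[i],
                            res$resno[i], res$x[i], res$y[i], res$z[i]))
    } else {
      lines <- c(lines, fmt(serial, "CA", res$aa[i], res$chain[i],
                            res$resno[i], res$x[i], res$y[i], res$z[i] + 1.0))
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, "CB", res$aa[i], res$chain[i],
                            res$resno[i], res$x[i], res$y[i], res$z[i]))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.labeled_structure <- function(x, ...) {
  r <- x$residues
  cat("<labeled_structure> ", x$structure_id, " (", x$topology_class, ")\n",
      sep = "")
  cat("  ", nrow(r), " residues in ", length(unique(r$chain)), " chain(s); ",
      sum(r$region == "TM"), " TM / ", sum(r$region == "EM"), " EM / ",
      sum(r$region == "UNASSIGNED"), " unassigned\n", sep = "")
  invisible(x)
}
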