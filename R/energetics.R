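#' Global folding free energy of a structure under a potential
#'
#' Half-sum of the potential over all ordered residue pairs separated
#' by more than one position along the chain (so each unordered pair
#' counts once for `sds`, and once per endpoint type with weight 1/2
#' for `sd`).  Distances are binned with the table's own scheme;
#' overflow-bin values are included as stored.  The region labels of
#' the residues play no role here: the table's region is fixed by its
#' derivation dataset and every residue is scored under it.
#'
#' @param structure a `labeled_structure` with at least 3 residues.
#' @param table a `potential_table` of flavor `"sd"` or `"sds"`.
#' @param inter_chain include inter-chain pairs (must match the
#'   pairing policy the table was derived with).
#' @return scalar energy in kcal/mol.
#' @export
folding_energy <- function(structure, table, inter_chain = FALSE) {
  prof <- per_residue_energy_one(structure, table, inter_chain)
  sum(prof)
}

# per-residue half-share contributions under one table
per_residue_energy_one <- function(structure, table, inter_chain = FALSE) {
  stopifnot(inherits(structure, "labeled_structure"),
            inherits(table, "potential_table"))
  if (!table$flavor %in% c("sd", "sds"))
    stop("energies require an sd or sds potential table")
  pairing <- if (inter_chain) "inter" else "intra"
  if (!is.null(table$pairing) && table$pairing != pairing)
    stop("pairing policy mismatch: table derived with '", table$pairing,
         "' pairs, energy requested with '", pairing, "'")
  res <- structure$residues
  if (nrow(res) < 3L) stop("structure must have at least 3 residues")
  pt <- structure_pair_table(structure, inter_chain = inter_chain)
  dG <- numeric(nrow(res))
  if (nrow(pt) == 0L) return(dG)
  bins <- distance_to_bin(pt$d, table$scheme)
  ok <- !is.na(bins)
  pt <- pt[ok, , drop = FALSE]
  bins <- bins[ok]
  si <- aa_index(res$aa[pt$i])
  sj <- aa_index(res$aa[pt$j])
  if (table$flavor == "sds") {
    w <- table$values[cbind(si, sj, bins)]
    # each unordered pair contributes W to both endpoints' half-shares
    inc_i <- 0.5 * w
    inc_j <- 0.5 * w
  } else {
    # ordered terms W(s_i, d_ij) and W(s_j, d_ij), each halved
    inc_i <- 0.5 * table$values[cbind(si, bins)]
    inc_j <- 0.5 * table$values[cbind(sj, bins)]
  }
  dG <- dG + unname(tapply_sum(inc_i, pt$i, nrow(res))) +
    unname(tapply_sum(inc_j, pt$j, nrow(res)))
  dG
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Per-residue folding energies under the four potential flavors
#'
#' For residue `i`, its contribution is half the sum of the pair
#' potential over all partners `j` with `|i - j| > 1` in the whole
#' structure, regardless of the partner's region label; summed over
#' residues these contributions reproduce the global folding free
#' energy exactly.
#'
#' @param structure a `labeled_structure`.
#' @param tables named list with elements `sd_TM`, `sds_TM`, `sd_EM`,
#'   `sds_EM` (each a `potential_table`); any subset is allowed.
#' @param inter_chain pairing policy, as in [folding_energy()].
#' @return an `energy_profile`: data frame with one row per residue
#'   (chain, seq_index, aa, region and one `dG_*` column per table)
#'   plus a `global` attribute holding the summed energies.
#' @export
per_residue_energies <- function(structure, tables, inter_chain = FALSE) {
  stopifnot(is.list(tables), length(tables) > 0)
  res <- structure$residues
  out <- res[, c("chain", "seq_index", "aa", "region")]
  glob <- numeric(0)
  for (nm in names(tables)) {
    dG <- per_residue_energy_one(structure, tables[[nm]], inter_chain)
    out[[paste0("dG_", nm)]] <- dG
    glob[nm] <- sum(dG)
  }
  attr(out, "global") <- glob
  attr(out, "structure_id") <- structure$structure_id
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Leave-one-out potential derivation
#'
#' Rebuilds a potential with one structure's contribution removed:
#' the held-out protein's raw counts are subtracted from the pooled
#' raw counts, then smoothing and the occurrence threshold are
#' re-applied (the threshold is nonlinear, so it cannot be carried
#' over from the full table).  Equivalent, bin for bin, to deriving
#' the potential from scratch on the dataset without that protein.
#'
#' @param all_counts raw pooled `pair_counts` with per-protein
#'   sub-counts.
#' @param held_out structure id to remove.
#' @param flavor `"sd"` or `"sds"`.
#' @param kBT Boltzmann factor (kcal/mol).
#' @param threshold,threshold_on occurrence guard, as in
#'   [derive_potential()].
#' @return a `potential_table` whose provenance records the excluded
#'   structure.
#' @export
loo_potentials <- function(all_counts, held_out, flavor = "sds",
                           kBT = 0.5925, threshold = 10,
                           threshold_on = "raw") {
  reduced <- subtract_protein_counts(all_counts, held_out)
  sm <- smooth_counts(reduced)
  tab <- derive_potential(sm, flavor = flavor, kBT = kBT,
                          threshold = threshold,
                          threshold_on = threshold_on)
  tab$provenance$excluded <- held_out
  tab
}

#' @export
print.energy_profile <- function(x, ...) {
  glob <- attr(x, "global")
  cat("<energy_profile> ", attr(x, "structure_id"), ": ", nrow(x),
      " residues\n", sep = "")
  for (nm in names(glob))
    cat(sprintf("  global %-8s %10.4f kcal/mol\n", nm, glob[nm]))
  invisible(x)
}
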