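#' Distance binning scheme
#'
#' Distances between side-chain geometric centers are discretized into
#' 23 regular bins of 0.3 Angstrom width covering [3.0, 9.9), plus one
#' overflow bin collecting all distances of 9.9 Angstrom and above
#' (bin index 24).  Distances below 3 Angstrom are either clamped into
#' the first bin (default; rare clash artifacts should not silently
#' vanish) or discarded.
#'
#' @param sub3 policy for d < 3 Angstrom: `"clamp_to_first"` or
#'   `"discard"`.
#' @return a `binning_scheme` object.
#' @export
binning_scheme <- function(sub3 = c("clamp_to_first", "discard")) {
  sub3 <- match.arg(sub3)
  structure(list(lower = 3.0, width = 0.3, n_regular = 23L,
                 n_bins = 24L, sub3 = sub3,
                 edges = 3.0 + 0.3 * (0:23)),
            class = "binning_scheme")
}

#' Map distances to bin indices
#'
#' @param d numeric vector of distances (Angstrom), finite and >= 0.
#' @param scheme a [binning_scheme()].
#' @return integer bin indices in 1..24 (R indexing; the overflow bin
#'   is 24).  Under the `discard` policy, sub-3 distances map to `NA`.
#' @export
distance_to_bin <- function(d, scheme = binning_scheme()) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  # epsilon guards the half-open bin edges against float error
  # (3.3 - 3.0 is slightly below 0.3 in double precision)
  b <- floor((d - scheme$lower) / scheme$width + 1e-9) + 1L
  b[d >= 9.9] <- 24L
  low <- d < scheme$lower
  if (any(low)) {
    if (scheme$sub3 == "clamp_to_first") b[low] <- 1L
    else b[low] <- NA_integer_
  }
  as.integer(b)
}

bin_lower_edges <- function(scheme = binning_scheme())
  c(scheme$lower + scheme$width * 0:22, 9.9)

new_pair_counts <- function(n_pair, region, scheme, smoothed = FALSE,
                            per_protein = NULL, flavor = "aa",
                            labels = AA3, raw_pair = NULL,
                            ref_dist = NULL, ref_total = NULL,
                            pairing = "intra") {
  structure(list(region = region, scheme = scheme, flavor = flavor,
                 labels = labels, n_pair = n_pair, smoothed = smoothed,
                 per_protein = per_protein, raw_pair = raw_pair,
                 ref_dist = ref_dist, ref_total = ref_total,
                 pairing = pairing),
            class = "pair_counts")
}

#' Construct a pair-count table from a raw count array
#'
#' Mainly for tests and simulation: wraps a symmetric `m x m x 24`
#' count array (types x types x distance bins) into a `pair_counts`
#' object with marginals computed by summation.
#'
#' @param n_pair numeric array, symmetric in its first two dimensions.
#' @param region region tag (`"TM"`, `"EM"` or `"GL"`).
#' @param scheme binning scheme.
#' @param labels dimension labels (amino acids or group names).
#' @param smoothed whether the array already holds smoothed counts.
#' @return a `pair_counts` object.
#' @export
pair_counts <- function(n_pair, region = "TM", scheme = binning_scheme(),
                        labels = AA3, smoothed = FALSE) {
  stopifnot(length(dim(n_pair)) == 3L, dim(n_pair)[3] == scheme$n_bins,
            dim(n_pair)[1] == dim(n_pair)[2])
  if (max(abs(n_pair - aperm(n_pair, c(2, 1, 3)))) > 1e-9)
    stop("pair-count array must be symmetric in its first two dimensions")
  if (any(n_pair < 0)) stop("negative counts")
  new_pair_counts(n_pair, region, scheme, smoothed = smoothed,
                  labels = labels)
}

# marginals, all derived from the stored (raw or smoothed) table:
#   n_single[s, b]  = sum_s2 n_pair[s, s2, b]   (endpoint counts)
#   n_pair_aa[s1,s2]= sum_b  n_pair[s1, s2, b]
#   n_dist[b]       = sum_{s1,s2} n_pair        (2x pair events)
#   n_total         = sum of everything
counts_marginals <- function(pc) {
  np <- pc$n_pair
  list(n_single = apply(np, c(1, 3), sum),
       n_pair_aa = apply(np, c(1, 2), sum),
       n_dist = apply(np, 3, sum),
       n_single_aa = apply(np, 1, sum),
       n_total = sum(np))
}

# eligible residue pairs of one structure under a pairing policy:
# within a chain, |seq_index difference| > 1; inter-chain pairs are
# excluded by default (flag includes them all, no separation rule)
structure_pair_table <- function(structure, inter_chain = FALSE) {
  res <- structure$residues
  out <- vector("list", 0)
  chains <- unique(res$chain)
  for (ch in chains) {
    idx <- which(res$chain == ch)
    if (length(idx) < 2L) next
    D <- as.matrix(stats::dist(as.matrix(res[idx, c("x", "y", "z")])))
    ut <- which(upper.tri(D), arr.ind = TRUE)
    sep <- abs(res$seq_index[idx[ut[, 2]]] - res$seq_index[idx[ut[, 1]]])
    keep <- sep > 1L
    if (!any(keep)) next
    out[[length(out) + 1L]] <-
      data.frame(i = idx[ut[keep, 1]], j = idx[ut[keep, 2]],
                 d = D[ut[keep, , drop = FALSE]])
  }
  if (inter_chain && length(chains) > 1L) {
    xyz <- as.matrix(res[, c("x", "y", "z")])
    for (a in seq_along(chains)[-length(chains)]) for (b in (a + 1):length(chains)) {
      ia <- which(res$chain == chains[a]); ib <- which(res$chain == chains[b])
      D <- sqrt(outer(rowSums(xyz[ia, , drop = FALSE]^2), rep(1, length(ib))) +
                outer(rep(1, length(ia)), rowSums(xyz[ib, , drop = FALSE]^2)) -
                2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE]))
      out[[length(out) + 1L]] <-
        data.frame(i = rep(ia, times = length(ib)),
                   j = rep(ib, each = length(ia)),
                   d = as.numeric(D))
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      d = numeric()))
  do.call(rbind, out)
}

tabulate_pairs <- function(s1, s2, bins, m, n_bins) {
  idx <- (bins - 1L) * m * m + (s2 - 1L) * m + s1
  idx2 <- (bins - 1L) * m * m + (s1 - 1L) * m + s2
  array(tabulate(c(idx, idx2), nbins = m * m * n_bins),
        dim = c(m, m, n_bins))
}

#' Accumulate regional pair counts over a structure set
#'
#' For every eligible residue pair (same chain, separated by more than
#' one position; optionally all inter-chain pairs) with both residues
#' labeled with the requested region, the count table
#' `n(s1, s2, bin(d))` is incremented symmetrically (double storage:
#' each unordered pair event adds one to `[s1,s2,b]` and one to
#' `[s2,s1,b]`, hence two to a diagonal cell).  Single-type counts
#' `n(s, d)` and all other marginals are marginals of this table.
#' Per-structure sub-counts are retained for leave-one-out
#' subtraction.
#'
#' @param structures list of `labeled_structure` with regions
#'   resolved.
#' @param region `"TM"`, `"EM"` or `"GL"` (the tag is whatever the
#'   caller's dataset represents; both residues must carry it, except
#'   `"GL"` which takes all residues of globular reference
#'   structures).
#' @param scheme binning scheme.
#' @param inter_chain include inter-chain pairs.
#' @return a raw `pair_counts` object with `per_protein` sub-counts.
#' @export
accumulate_pair_counts <- function(structures, region,
                                   scheme = binning_scheme(),
                                   inter_chain = FALSE) {
  if (length(structures) == 0L) stop("empty structure list")
  m <- length(AA3)
  pooled <- array(0, dim = c(m, m, scheme$n_bins))
  per_protein <- list()
  for (s in structures) {
    res <- s$residues
    if (region != "GL" && any(res$region == "UNASSIGNED"))
      stop("structure ", s$structure_id, " has unassigned regions")
    pt <- structure_pair_table(s, inter_chain = inter_chain)
    tab <- array(0, dim = c(m, m, scheme$n_bins))
    if (nrow(pt)) {
      if (region == "GL") keep <- rep(TRUE, nrow(pt))
      else keep <- res$region[pt$i] == region & res$region[pt$j] == region
      pt <- pt[keep, , drop = FALSE]
      if (nrow(pt)) {
        bins <- distance_to_bin(pt$d, scheme)
        ok <- !is.na(bins)
        if (any(ok))
          tab <- tabulate_pairs(aa_index(res$aa[pt$i[ok]]),
                                aa_index(res$aa[pt$j[ok]]),
                                bins[ok], m, scheme$n_bins)
      }
    }
    per_protein[[s$structure_id]] <- tab
    pooled <- pooled + tab
  }
  dimnames(pooled) <- list(AA3, AA3, NULL)
  new_pair_counts(pooled, region, scheme, per_protein = per_protein,
                  pairing = if (inter_chain) "inter" else "intra")
}

smoothing_matrix <- function(n_regular = 23L, beta = 4L, alpha = 4 / 3) {
  S <- diag(n_regular)
  base <- 1 / alpha                # exactly 3/4 for the default alpha
  for (i in 1:beta) {
    w <- base^i
    S <- S + w * (row(S) - col(S) == i) + w * (col(S) - row(S) == i)
  }
  S
}

#' Smooth sparse pair counts across neighboring distance bins
#'
#' Each regular bin's count is replaced by a weighted sum over its
#' neighborhood: `n^(d) = sum_{i=1..4} alpha^-i n(d-i) + n(d) +
#' sum_{i=1..4} alpha^-i n(d+i)` with `alpha = 4/3` (weights
#' `(3/4)^i`).  Out-of-range neighbor terms are dropped (boundary
#' truncation).  The overflow bin aggregates an unbounded distance
#' range and is excluded from the neighborhood, both as source and as
#' recipient; its count is carried through unchanged.  Marginals are
#' recomputed from the smoothed table.  The raw table is retained so
#' the occurrence threshold can optionally be evaluated on raw counts.
#'
#' @param raw a raw `pair_counts` object.
#' @param beta neighborhood half-width in bins.
#' @param alpha geometric decay base of the weights.
#' @return a smoothed `pair_counts` object.
#' @export
smooth_counts <- function(raw, beta = 4L, alpha = 4 / 3) {
  stopifnot(inherits(raw, "pair_counts"))
  if (raw$smoothed) stop("counts are already smoothed")
  nb <- raw$scheme$n_bins
  nr <- raw$scheme$n_regular
  S <- smoothing_matrix(nr, beta, alpha)
  np <- raw$n_pair
  m <- dim(np)[1]
  flat <- matrix(np[, , 1:nr], nrow = m * m, ncol = nr)
  sm <- array(0, dim = dim(np), dimnames = dimnames(np))
  sm[, , 1:nr] <- array(flat %*% t(S), dim = c(m, m, nr))
  sm[, , nb] <- np[, , nb]
  # a stored full-dataset reference (group tables) is smoothed with
  # the same kernel so numerator and reference stay commensurate
  ref <- raw$ref_dist
  if (!is.null(ref)) ref <- c(as.numeric(S %*% ref[1:nr]), ref[nb])
  out <- new_pair_counts(sm, raw$region, raw$scheme, smoothed = TRUE,
                         per_protein = raw$per_protein,
                         flavor = raw$flavor, labels = raw$labels,
                         raw_pair = np, ref_dist = ref,
                         ref_total = if (is.null(ref)) NULL else sum(ref),
                         pairing = raw$pairing)
  out
}

#' Pool pair counts over an amino-acid group pair
#'
#' Counts residue pairs with one member in each group, shifting each
#' continuous distance by the side-chain-radius excess of both
#' endpoints over the smallest member of their group
#' (`d - delta(s_i) - delta(s_j)`) before binning, so that members of
#' different size contribute to a comparable distance axis.  Shifted
#' distances below 3 Angstrom follow the scheme's sub-3 policy.
#'
#' The reference distance distribution for the group potential
#' (`n(d)`, `n`) is taken from the full unshifted all-pair counts of
#' the same region dataset and stored alongside the pooled table.
#'
#' @param structures list of labeled structures with regions resolved.
#' @param region region tag.
#' @param group1,group2 `group_def` objects (may be identical for a
#'   self-pair).
#' @param scheme binning scheme.
#' @param inter_chain include inter-chain pairs.
#' @return a raw `pair_counts` with `flavor = "group"`, a `1 x 1 x 24`
#'   table over the group pair, and reference marginals attached.
#' @export
pool_group_counts <- function(structures, region, group1, group2,
                              scheme = binning_scheme(),
                              inter_chain = FALSE) {
  stopifnot(inherits(group1, "group_def"), inherits(group2, "group_def"))
  shared <- intersect(group1$members, group2$members)
  if (length(shared) && !identical(sort(group1$members), sort(group2$members)))
    stop("groups must be disjoint or identical")
  full <- accumulate_pair_counts(structures, region, scheme,
                                 inter_chain = inter_chain)
  mg <- counts_marginals(full)
  tab <- array(0, dim = c(1, 1, scheme$n_bins))
  per_protein <- list()
  delta <- function(g, aa) unname(g$delta[aa])
  for (s in structures) {
    res <- s$residues
    pt <- structure_pair_table(s, inter_chain = inter_chain)
    ptab <- array(0, dim = c(1, 1, scheme$n_bins))
    if (nrow(pt)) {
      if (region == "GL") inreg <- rep(TRUE, nrow(pt))
      else inreg <- res$region[pt$i] == region & res$region[pt$j] == region
      ai <- res$aa[pt$i]; aj <- res$aa[pt$j]
      self_pair <- identical(sort(group1$members), sort(group2$members))
      fwd <- ai %in% group1$members & aj %in% group2$members
      bwd <- if (self_pair) rep(FALSE, length(fwd))
             else ai %in% group2$members & aj %in% group1$members
      sel <- inreg & (fwd | bwd)
      if (any(sel)) {
        dsh <- numeric(sum(sel))
        f <- fwd[sel]
        dsh[f] <- pt$d[sel][f] - delta(group1, ai[sel][f]) -
          delta(group2, aj[sel][f])
        dsh[!f] <- pt$d[sel][!f] - delta(group2, ai[sel][!f]) -
          delta(group1, aj[sel][!f])
        bins <- distance_to_bin(pmax(dsh, 0), scheme)
        bins <- bins[!is.na(bins)]
        # block-sum convention: pooling the (g1, g2) block of the
        # symmetric 20x20x24 table gives 1 event per cross-group pair
        # and 2 per pair when the groups are identical
        mult <- if (self_pair) 2 else 1
        if (length(bins))
          ptab[1, 1, ] <- mult * tabulate(bins, nbins = scheme$n_bins)
      }
    }
    per_protein[[s$structure_id]] <- ptab
    tab <- tab + ptab
  }
  lab <- paste(group1$name, group2$name, sep = ":")
  new_pair_counts(tab, region, scheme, per_protein = per_protein,
                  flavor = "group", labels = lab,
                  ref_dist = mg$n_dist, ref_total = mg$n_total,
                  pairing = if (inter_chain) "inter" else "intra")
}

#' Leave-one-out subtraction on raw counts
#'
#' Removes one structure's per-protein contribution from a pooled raw
#' count table.  Smoothing and thresholding must be re-applied
#' afterwards (smoothing is linear but the occurrence threshold is
#' not, so subtraction happens on raw counts).
#'
#' @param counts raw `pair_counts` with `per_protein` sub-counts.
#' @param structure_id the structure to remove.
#' @return a raw `pair_counts` over the remaining structures.
#' @export
subtract_protein_counts <- function(counts, structure_id) {
  stopifnot(inherits(counts, "pair_counts"))
  if (counts$smoothed)
    stop("leave-one-out subtraction operates on raw counts")
  if (is.null(counts$per_protein) ||
      !structure_id %in% names(counts$per_protein))
    stop("unknown structure_id: ", structure_id)
  np <- counts$n_pair - counts$per_protein[[structure_id]]
  if (min(np) < -1e-9)
    stop("internal inconsistency: subtraction produced negative counts")
  np[np < 0] <- 0
  pp <- counts$per_protein[setdiff(names(counts$per_protein), structure_id)]
  rd <- counts$ref_dist
  # group tables carry a full-dataset reference; it must shrink too,
  # but the per-protein reference is not retained for groups, so the
  # caller (loo on groups) rebuilds instead.  Plain aa tables have no
  # stored reference.
  new_pair_counts(np, counts$region, counts$scheme,
                  per_protein = pp, flavor = counts$flavor,
                  labels = counts$labels, ref_dist = rd,
                  ref_total = counts$ref_total, pairing = counts$pairing)
}

#' Serialize counts to a TSV bundle
#'
#' Long format: `region  aa1  aa2  bin_lower_edge  count`, raw counts
#' only (one row per non-empty cell of the upper triangle).
#'
#' @param counts a `pair_counts`.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  np <- if (counts$smoothed) counts$raw_pair else counts$n_pair
  edges <- bin_lower_edges(counts$scheme)
  m <- dim(np)[1]
  rows <- which(np > 0, arr.ind = TRUE)
  rows <- rows[rows[, 1] <= rows[, 2], , drop = FALSE]
  labs <- if (m == length(AA3)) AA3 else counts$labels
  df <- data.frame(region = counts$region,
                   aa1 = labs[rows[, 1]], aa2 = labs[rows[, 2]],
                   bin_lower_edge = edges[rows[, 3]],
                   count = np[rows])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV bundle written by [write_counts_tsv()]
#' @param path file path.
#' @return a raw `pair_counts` (per-protein sub-counts are not part of
#'   the serialized form).
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  scheme <- binning_scheme()
  m <- length(AA3)
  np <- array(0, dim = c(m, m, scheme$n_bins), dimnames = list(AA3, AA3, NULL))
  b <- match(round(df$bin_lower_edge, 6), round(bin_lower_edges(scheme), 6))
  i1 <- aa_index(df$aa1); i2 <- aa_index(df$aa2)
  np[cbind(i1, i2, b)] <- df$count
  np[cbind(i2, i1, b)] <- df$count
  new_pair_counts(np, df$region[1], scheme)
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> region ", x$region, ", flavor ", x$flavor,
      if (x$smoothed) ", smoothed" else ", raw",
      "; total count ", format(sum(x$n_pair)), "\n", sep = "")
  if (!is.null(x$per_protein))
    cat("  per-protein sub-counts for ", length(x$per_protein),
        " structure(s)\n", sep = "")
  invisible(x)
}
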