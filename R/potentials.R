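#' Derive distance-dependent statistical potentials from counts
#'
#' Inverse-Boltzmann potentials over 0.3-Angstrom distance bins:
#' \deqn{\Delta W(s_1,s_2,d) = -k_B T \,\ln\frac{n(s_1,s_2,d)\, n}{n(s_1,s_2)\, n(d)}}
#' and analogously \eqn{\Delta W(s,d)} with the single-type marginals.
#' Bins whose occurrence count falls below the guard threshold (10 by
#' default), or where any reference term vanishes, yield
#' \eqn{\Delta W = 0} and are recorded in a mask; masked bins
#' contribute exactly zero to every downstream energy.
#'
#' The counts must be smoothed first (see [smooth_counts()]).  The
#' occurrence guard is the first layer of the computation and by
#' default inspects the retained raw counts: smoothing spreads
#' kernel tails into bins that contain essentially no genuine
#' occurrences, and thresholding the smoothed counts would let such
#' bins through.  `threshold_on = "smoothed"` evaluates the guard on
#' the smoothed counts instead.
#'
#' @param counts a smoothed `pair_counts` object.
#' @param flavor `"sd"` (single residue type vs distance) or `"sds"`
#'   (type pair vs distance).
#' @param kBT Boltzmann factor in kcal/mol; default 0.5925 (room
#'   temperature, 298.15 K).
#' @param threshold minimum occurrence count for a bin to be trusted.
#' @param threshold_on `"smoothed"` or `"raw"`.
#' @return a `potential_table` with fields `flavor`, `region`, `kBT`,
#'   `values` (matrix `20 x 24` for sd, array `20 x 20 x 24` for sds),
#'   `mask` (TRUE where suppressed), `provenance`.
#' @export
derive_potential <- function(counts, flavor = c("sds", "sd"),
                             kBT = 0.5925, threshold = 10,
                             threshold_on = c("raw", "smoothed")) {
  flavor <- match.arg(flavor)
  threshold_on <- match.arg(threshold_on)
  stopifnot(inherits(counts, "pair_counts"))
  if (kBT <= 0) stop("kBT must be positive")
  if (!counts$smoothed)
    stop("counts must be smoothed (run smooth_counts first)")
  mg <- counts_marginals(counts)
  guard_src <- if (threshold_on == "raw") {
    if (is.null(counts$raw_pair)) stop("raw counts not retained")
    raw <- new_pair_counts(counts$raw_pair, counts$region, counts$scheme)
    counts_marginals(raw)
  } else mg
  if (flavor == "sds") {
    num <- mg$n_pair_aa                     # n(s1,s2)
    tab <- counts$n_pair
    gtab <- if (threshold_on == "raw") counts$raw_pair else tab
    ratio <- sweep(tab, 3, mg$n_dist, "/") * mg$n_total
    ratio <- sweep(ratio, c(1, 2), num, "/")
    denom_ok <- outer(num > 0, mg$n_dist > 0)
  } else {
    tab <- mg$n_single                      # n(s, d)
    gtab <- if (threshold_on == "raw") guard_src$n_single else tab
    ratio <- sweep(sweep(tab, 2, mg$n_dist, "/") * mg$n_total,
                   1, mg$n_single_aa, "/")
    denom_ok <- outer(mg$n_single_aa > 0, mg$n_dist > 0)
  }
  mask <- gtab < threshold | !denom_ok | tab <= 0
  values <- array(0, dim = dim(ratio), dimnames = dimnames(ratio))
  values[!mask] <- -kBT * log(ratio[!mask])
  new_potential_table(flavor, counts$region, kBT, values, mask,
                      scheme = counts$scheme, labels = counts$labels,
                      pairing = counts$pairing,
                      provenance = list(threshold = threshold,
                                        threshold_on = threshold_on,
                                        smoothed = TRUE))
}

new_potential_table <- function(flavor, region, kBT, values, mask,
                                scheme, labels, pairing = "intra",
                                provenance = list()) {
  structure(list(flavor = flavor, region = region, kBT = kBT,
                 values = values, mask = mask, scheme = scheme,
                 labels = labels, pairing = pairing,
                 provenance = provenance),
            class = "potential_table")
}

#' Derive a group potential from pooled shifted counts
#'
#' Applies the same inverse-Boltzmann formula to a group-pooled count
#' table (see [pool_group_counts()]): the numerator counts and the
#' group-pair marginal come from the pooled shifted table, while the
#' reference distance distribution `n(d), n` comes from the full
#' unshifted all-pair counts of the same region dataset, which the
#' pooled object carries.
#'
#' @param group_counts smoothed `pair_counts` of flavor `"group"`.
#' @inheritParams derive_potential
#' @return a `potential_table` of flavor `"group"` with a length-24
#'   value vector.
#' @export
derive_group_potential <- function(group_counts, kBT = 0.5925,
                                   threshold = 10,
                                   threshold_on = c("raw", "smoothed")) {
  threshold_on <- match.arg(threshold_on)
  stopifnot(inherits(group_counts, "pair_counts"),
            group_counts$flavor == "group")
  if (kBT <= 0) stop("kBT must be positive")
  if (!group_counts$smoothed)
    stop("counts must be smoothed (run smooth_counts first)")
  if (is.null(group_counts$ref_dist))
    stop("group counts lack the full-dataset reference marginals")
  nh <- group_counts$n_pair[1, 1, ]
  raw <- if (!is.null(group_counts$raw_pair)) group_counts$raw_pair[1, 1, ]
         else nh
  n_gg <- sum(nh)
  n_dist <- group_counts$ref_dist
  n_tot <- group_counts$ref_total
  gval <- if (threshold_on == "raw") raw else nh
  mask <- gval < threshold | n_dist <= 0 | nh <= 0 | n_gg <= 0
  values <- numeric(length(nh))
  ok <- !mask
  values[ok] <- -kBT * log(nh[ok] * n_tot / (n_gg * n_dist[ok]))
  new_potential_table("group", group_counts$region, kBT, values, mask,
                      scheme = group_counts$scheme,
                      labels = group_counts$labels,
                      pairing = group_counts$pairing,
                      provenance = list(threshold = threshold,
                                        threshold_on = threshold_on))
}

#' Compare two potential tables bin by bin
#'
#' Differences are defined only where both tables are unmasked; the
#' summary reports the mean shift over comparable bins and the
#' location and depth of each table's minimum.
#'
#' @param a,b `potential_table` objects of the same flavor and
#'   indexing.
#' @return list with `difference` (a - b, `NA` where not comparable),
#'   `mean_shift`, `n_comparable`, and per-table minima
#'   (`min_a`, `min_b`: value and bin lower edge).
#' @export
potential_difference <- function(a, b) {
  stopifnot(inherits(a, "potential_table"), inherits(b, "potential_table"))
  if (a$flavor != b$flavor || !identical(dim2(a$values), dim2(b$values)))
    stop("potential tables have mismatched flavors or shapes")
  comparable <- !a$mask & !b$mask
  diffs <- a$values - b$values
  diffs[!comparable] <- NA_real_
  edges <- bin_lower_edges(a$scheme)
  minloc <- function(p) {
    v <- p$values
    v[p$mask] <- NA_real_
    if (all(is.na(v))) return(list(value = NA_real_, edge = NA_real_))
    i <- which.min(v)
    bin <- arrayInd(i, dim2(v))[, length(dim2(v))]
    list(value = v[i], edge = edges[bin])
  }
  list(difference = diffs,
       mean_shift = mean(diffs, na.rm = TRUE),
       n_comparable = sum(comparable),
       min_a = minloc(a), min_b = minloc(b))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Write a potential table as TSV
#'
#' Long format `flavor  region  s1  s2  bin_lower_edge_A
#' deltaW_kcal_mol  masked`; values round-trip bit-exactly through
#' [read_potential_tsv()].
#'
#' @param table a `potential_table`.
#' @param path output path.
#' @export
write_potential_tsv <- function(table, path) {
  edges <- bin_lower_edges(table$scheme)
  v <- table$values
  if (table$flavor == "sds") {
    idx <- which(slice.index(v, 3) > 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
    df <- data.frame(flavor = table$flavor, region = table$region,
                     s1 = AA3[idx[, 1]], s2 = AA3[idx[, 2]],
                     bin_lower_edge_A = edges[idx[, 3]],
                     deltaW_kcal_mol = sprintf("%.17g", v[idx]),
                     masked = as.integer(table$mask[idx]))
  } else if (table$flavor == "sd") {
    idx <- expand.grid(s = seq_len(nrow(v)), b = seq_len(ncol(v)))
    df <- data.frame(flavor = table$flavor, region = table$region,
                     s1 = AA3[idx$s], s2 = "-",
                     bin_lower_edge_A = edges[idx$b],
                     deltaW_kcal_mol = sprintf("%.17g", v[cbind(idx$s, idx$b)]),
                     masked = as.integer(table$mask[cbind(idx$s, idx$b)]))
  } else {
    df <- data.frame(flavor = table$flavor, region = table$region,
                     s1 = table$labels, s2 = "-",
                     bin_lower_edge_A = edges,
                     deltaW_kcal_mol = sprintf("%.17g", v),
                     masked = as.integer(table$mask))
  }
  hdr <- sprintf("# kBT=%.17g", table$kBT)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a potential table written by [write_potential_tsv()]
#' @param path file path.
#' @return a `potential_table`.
#' @export
read_potential_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  kBT <- as.numeric(sub("# kBT=", "", hdr, fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "numeric", "character",
                                         "integer"))
  scheme <- binning_scheme()
  edges <- bin_lower_edges(scheme)
  b <- match(round(df$bin_lower_edge_A, 6), round(edges, 6))
  val <- as.numeric(df$deltaW_kcal_mol)
  flavor <- df$flavor[1]
  if (flavor == "sds") {
    v <- array(0, dim = c(20, 20, 24), dimnames = list(AA3, AA3, NULL))
    msk <- array(TRUE, dim = c(20, 20, 24))
    i1 <- aa_index(df$s1); i2 <- aa_index(df$s2)
    v[cbind(i1, i2, b)] <- val; v[cbind(i2, i1, b)] <- val
    msk[cbind(i1, i2, b)] <- df$masked == 1L
    msk[cbind(i2, i1, b)] <- df$masked == 1L
    labels <- AA3
  } else if (flavor == "sd") {
    v <- matrix(0, 20, 24, dimnames = list(AA3, NULL))
    msk <- matrix(TRUE, 20, 24)
    i1 <- aa_index(df$s1)
    v[cbind(i1, b)] <- val
    msk[cbind(i1, b)] <- df$masked == 1L
    labels <- AA3
  } else {
    v <- numeric(24); msk <- rep(TRUE, 24)
    v[b] <- val; msk[b] <- df$masked == 1L
    labels <- df$s1[1]
  }
  new_potential_table(flavor, df$region[1], kBT, v, msk, scheme, labels)
}

#' @export
print.potential_table <- function(x, ...) {
  cat("<potential_table> flavor ", x$flavor, ", region ", x$region,
      ", kBT = ", x$kBT, " kcal/mol\n", sep = "")
  cat("  ", sum(!x$mask), " unmasked bins of ", length(x$mask),
      "; range [", sprintf("%.3f", suppressWarnings(min(x$values[!x$mask]))),
      ", ", sprintf("%.3f", suppressWarnings(max(x$values[!x$mask]))),
      "] kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
plot.potential_table <- function(x, pair = NULL, ...) {
  edges <- bin_lower_edges(x$scheme)
  mid <- edges + x$scheme$width / 2
  if (x$flavor == "group") {
    y <- x$values
    y[x$mask] <- NA
    ttl <- paste0(x$labels, " (", x$region, ")")
  } else if (x$flavor == "sds") {
    if (is.null(pair)) stop("specify pair = c(aa1, aa2) for sds tables")
    i <- aa_index(pair)
    y <- x$values[i[1], i[2], ]
    y[x$mask[i[1], i[2], ]] <- NA
    ttl <- paste0(pair[1], "-", pair[2], " (", x$region, ")")
  } else {
    if (is.null(pair)) stop("specify pair = aa for sd tables")
    i <- aa_index(pair[1])
    y <- x$values[i, ]
    y[x$mask[i, ]] <- NA
    ttl <- paste0(pair[1], " (", x$region, ")")
  }
  graphics::plot(mid[1:23], y[1:23], type = "b", pch = 16,
                 xlab = "distance (A)",
                 ylab = expression(Delta * W ~ "(kcal/mol)"),
                 main = ttl, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
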