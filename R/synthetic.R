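#' Configuration for the synthetic membrane-protein generator
#'
#' The generator emulates the statistical structure of a membrane
#' protein dataset split into trans- and extramembrane regions:
#' contiguous TM segments (ideal helices spanning a virtual slab, or
#' strands on a cylinder in barrel mode) connected by compact
#' extramembrane segments; region-dependent amino-acid composition
#' (aliphatic/aromatic enrichment in TM, charged/polar enrichment in
#' EM); and planted distance-specific pair contacts whose frequency
#' differs between regions.
#'
#' Planted contact target distances are expressed in the group frame
#' (i.e. after side-chain-radius correction): a planted pair of types
#' `(s1, s2)` is placed at geometric center distance
#' `target + delta(s1) + delta(s2)`, so that larger members form the
#' same contact at proportionally larger center distance.
#'
#' @param n_proteins number of structures.
#' @param topology `"alpha_helical"` or `"beta_barrel"` (per-protein
#'   mix via `alpha_fraction`).
#' @param alpha_fraction fraction of alpha-helical proteins when both
#'   topologies are generated.
#' @param n_tm_segments TM helices (or strand pairs in barrel mode).
#' @param tm_len,em_len residues per TM segment / per EM segment.
#' @param comp_TM,comp_EM named amino-acid probability vectors
#'   (must sum to 1).
#' @param contacts list of planted contacts, each a list with fields
#'   `group1`, `group2` (group names from [standard_groups()] or
#'   member vectors), `region`, `distance` (group-frame target,
#'   Angstrom, in [3, 9.9)), `prob` (excess probability in [0, 1]).
#' @param sigma geometric noise standard deviation (Angstrom).
#' @param radii side-chain radius table for the group-frame
#'   correction.
#' @return a `fixture_config` object.
#' @export
fixture_config <- function(n_proteins = 50L,
                           topology = "alpha_helical",
                           alpha_fraction = 1,
                           n_tm_segments = 4L,
                           tm_len = 21L, em_len = 14L,
                           comp_TM = default_composition("TM"),
                           comp_EM = default_composition("EM"),
                           contacts = default_contacts(),
                           sigma = 0.25,
                           radii = default_residue_radii()) {
  stopifnot(abs(sum(comp_TM) - 1) < 1e-6, abs(sum(comp_EM) - 1) < 1e-6,
            all(names(comp_TM) == AA3), all(names(comp_EM) == AA3),
            n_proteins >= 1, tm_len >= 4, em_len >= 4)
  for (ct in contacts) {
    if (ct$distance < 3.0 || ct$distance >= 9.9)
      stop("planted contact distance must lie in [3.0, 9.9)")
    if (ct$prob < 0 || ct$prob > 1)
      stop("planted contact probability must lie in [0, 1]")
    if (!ct$region %in% c("TM", "EM")) stop("contact region must be TM or EM")
  }
  structure(list(n_proteins = as.integer(n_proteins), topology = topology,
                 alpha_fraction = alpha_fraction,
                 n_tm_segments = as.integer(n_tm_segments),
                 tm_len = as.integer(tm_len), em_len = as.integer(em_len),
                 comp_TM = comp_TM, comp_EM = comp_EM,
                 contacts = contacts, sigma = sigma, radii = radii),
            class = "fixture_config")
}

#' Region-dependent composition defaults
#'
#' Qualitative contrast between the membrane-embedded and
#' water-exposed datasets: aliphatic (Ile, Val, Leu) and aromatic
#' residues enriched in TM, charged and polar residues enriched in
#' EM.
#'
#' @param region `"TM"`, `"EM"`, or `"null"` (the average of the two,
#'   used for both regions of a non-separable null dataset).
#' @return named probability vector over the 20 amino acids.
#' @export
default_composition <- function(region = c("TM", "EM", "null")) {
  region <- match.arg(region)
  tm <- c(ALA = .09, ARG = .01, ASN = .02, ASP = .01, CYS = .02,
          GLN = .01, GLU = .01, GLY = .07, HIS = .01, ILE = .11,
          LEU = .16, LYS = .01, MET = .04, PHE = .08, PRO = .02,
          SER = .04, THR = .05, TRP = .04, TYR = .05, VAL = .15)
  em <- c(ALA = .07, ARG = .06, ASN = .05, ASP = .07, CYS = .01,
          GLN = .05, GLU = .08, GLY = .07, HIS = .02, ILE = .04,
          LEU = .08, LYS = .07, MET = .02, PHE = .04, PRO = .05,
          SER = .07, THR = .06, TRP = .01, TYR = .04, VAL = .04)
  switch(region, TM = tm, EM = em, null = (tm + em) / 2)
}

#' Default planted contacts
#'
#' TM segments carry aliphatic core-packing contacts at short range
#' and salt bridges at 4 Angstrom; EM segments carry polar contacts
#' and their own salt bridges, so type-distance correlations differ
#' between regions and the localization task is learnable.
#'
#' @return list of contact specifications (see [fixture_config()]).
#' @export
default_contacts <- function() {
  list(
    list(group1 = "aliphatic", group2 = "aliphatic", region = "TM",
         distance = 4.6, prob = 0.5),
    list(group1 = "aliphatic", group2 = "aliphatic", region = "TM",
         distance = 5.2, prob = 0.5),
    list(group1 = "aliphatic", group2 = "aliphatic", region = "TM",
         distance = 5.8, prob = 0.5),
    list(group1 = "positive", group2 = "negative", region = "TM",
         distance = 4.0, prob = 0.3),
    list(group1 = "positive", group2 = "negative", region = "EM",
         distance = 4.0, prob = 0.3),
    list(group1 = "polar", group2 = "polar", region = "EM",
         distance = 4.6, prob = 0.5),
    list(group1 = "polar", group2 = "polar", region = "EM",
         distance = 5.2, prob = 0.5),
    list(group1 = "polar", group2 = "polar", region = "EM",
         distance = 5.8, prob = 0.5))
}

#' Matched null configuration
#'
#' Identical TM and EM composition (the average of the two defaults)
#' and no planted contacts: by construction the two regions are
#' statistically indistinguishable and any classifier should score at
#' chance.
#'
#' @param n_proteins number of structures.
#' @param ... further arguments passed to [fixture_config()].
#' @return a `fixture_config` with `separable = FALSE` semantics.
#' @export
null_fixture_config <- function(n_proteins = 50L, ...) {
  fixture_config(n_proteins = n_proteins,
                 comp_TM = default_composition("null"),
                 comp_EM = default_composition("null"),
                 contacts = list(), ...)
}

deg <- pi / 180

# ideal helix point cloud: side-chain centers on a cylinder of radius
# r_sc around a vertical axis, 1.5 A rise and 100 deg twist per
# residue
helix_centers <- function(n, axis, z0, dir, phase, r_sc = 4.0) {
  i <- 0:(n - 1)
  th <- phase + i * 100 * deg
  z <- z0 + dir * 1.5 * i
  cbind(axis[1] + r_sc * cos(th), axis[2] + r_sc * sin(th), z)
}

strand_centers <- function(n, theta, R, z0, dir, inward_first) {
  i <- 0:(n - 1)
  side <- ifelse((i + inward_first) %% 2 == 0, -1.8, 1.8)
  r <- R + side
  z <- z0 + dir * 3.3 * i
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Generate one synthetic membrane-protein structure
#'
#' Builds the geometry (TM helix bundle or beta-barrel spanning a
#' virtual slab, with compact extramembrane mini-bundles above and
#' below), samples residue types from the region compositions, plants
#' the configured contacts by re-sampling types at spatially
#' pre-selected close pairs (geometry is never distorted to force a
#' contact), and returns the labeled structure together with its PDB
#' text, annotation records and planting truth.
#'
#' @param config a `fixture_config`.
#' @param seed integer seed; every output is a pure function of
#'   `(config, seed)`.
#' @param id structure identifier.
#' @param topology override the config topology for this structure.
#' @return list with `structure` (a `labeled_structure`, regions
#'   assigned), `pdb_lines`, `annotation`, `truth`.
#' @export
generate_structure <- function(config, seed, id = "synth",
                               topology = config$topology) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(as.integer(seed))
  h <- config$n_tm_segments
  tm_len <- config$tm_len
  em_len <- config$em_len
  segs <- list()  # list of (region, side, centers)
  if (topology == "alpha_helical") {
    # facing side-chain centers of adjacent helices reach
    # Dpack - 2 * r_sc = 3.0 A, so the reference distance
    # distribution covers the whole binning range
    Dpack <- 11.0
    Rb <- if (h == 1) 0 else Dpack / (2 * sin(pi / h))
    ztop <- 1.5 * (tm_len - 1) / 2
    tm_axes <- lapply(seq_len(h) - 1L, function(k)
      c(Rb * cos(2 * pi * k / max(h, 1)), Rb * sin(2 * pi * k / max(h, 1))))
    for (k in seq_len(h)) {
      dir <- if (k %% 2 == 1) 1 else -1
      z0 <- if (dir == 1) -ztop else ztop
      segs[[length(segs) + 1L]] <-
        list(region = "TM", side = NA,
             centers = helix_centers(tm_len, tm_axes[[k]], z0, dir,
                                     phase = stats::runif(1, 0, 2 * pi)))
    }
  } else {
    ns <- max(8L, 2L * h)
    spacing <- 5.0
    R <- spacing / (2 * sin(pi / ns))
    tm_len <- max(8L, min(tm_len, 14L))
    ztop <- 3.3 * (tm_len - 1) / 2
    for (k in seq_len(ns)) {
      dir <- if (k %% 2 == 1) 1 else -1
      z0 <- if (dir == 1) -ztop else ztop
      segs[[length(segs) + 1L]] <-
        list(region = "TM", side = NA,
             centers = strand_centers(tm_len, 2 * pi * (k - 1) / ns, R,
                                      z0, dir, inward_first = k %% 2))
    }
    h <- ns
  }
  # extramembrane mini-bundles, laterally offset from the TM domain;
  # alternating sides so segments connect consecutive TM segments
  n_em <- h + 1L
  bot <- which(seq_len(n_em) %% 2 == 1L)
  top <- which(seq_len(n_em) %% 2 == 0L)
  ztop_all <- max(vapply(segs, function(s) max(s$centers[, 3]), 0))
  em_segs <- vector("list", n_em)
  place_bundle <- function(members, sign, center_xy) {
    nb <- length(members)
    if (nb == 0L) return(invisible(NULL))
    Rb2 <- if (nb == 1) 0 else 11.5 / (2 * sin(pi / nb))
    for (q in seq_len(nb)) {
      ax <- center_xy + c(Rb2 * cos(2 * pi * (q - 1) / max(nb, 1)),
                          Rb2 * sin(2 * pi * (q - 1) / max(nb, 1)))
      z0 <- sign * (ztop_all + 5)
      em_segs[[members[q]]] <<-
        list(region = "EM", side = if (sign < 0) "in" else "out",
             centers = helix_centers(em_len, ax, z0, sign,
                                     phase = stats::runif(1, 0, 2 * pi)))
    }
  }
  place_bundle(bot, -1, c(40, 0))
  place_bundle(top, +1, c(-40, 0))
  # interleave: EM1, TM1, EM2, TM2, ..., TM_h, EM_{h+1}
  ordered <- list()
  for (k in seq_len(h)) {
    ordered[[length(ordered) + 1L]] <- em_segs[[k]]
    ordered[[length(ordered) + 1L]] <- segs[[k]]
  }
  ordered[[length(ordered) + 1L]] <- em_segs[[n_em]]

  centers <- do.call(rbind, lapply(ordered, `[[`, "centers"))
  centers <- centers + matrix(stats::rnorm(length(centers), 0, config$sigma),
                              ncol = 3)
  region <- unlist(lapply(ordered, function(s) rep(s$region, nrow(s$centers))))
  side <- unlist(lapply(ordered, function(s)
    rep(if (is.na(s$side[1])) NA_character_ else s$side, nrow(s$centers))))
  n <- nrow(centers)

  # residue types: iid from the region compositions, then planted
  # contacts override types at pre-selected close pairs
  aa <- character(n)
  aa[region == "TM"] <- sample(AA3, sum(region == "TM"), replace = TRUE,
                               prob = config$comp_TM)
  aa[region == "EM"] <- sample(AA3, sum(region == "EM"), replace = TRUE,
                               prob = config$comp_EM)

  groups <- standard_groups(config$radii)
  pinned <- logical(n)
  planted <- list()
  if (length(config$contacts)) {
    D <- as.matrix(stats::dist(centers))
    ut <- which(upper.tri(D) & abs(row(D) - col(D)) > 1, arr.ind = TRUE)
    for (ct in config$contacts) {
      g1 <- resolve_group(ct$group1, groups, config$radii)
      g2 <- resolve_group(ct$group2, groups, config$radii)
      inreg <- region[ut[, 1]] == ct$region & region[ut[, 2]] == ct$region
      cand <- ut[inreg, , drop = FALSE]
      if (nrow(cand) == 0L) next
      # types first, then require the geometric distance to match the
      # size-corrected target for that member pair
      m1 <- sample(g1$members, nrow(cand), replace = TRUE)
      m2 <- sample(g2$members, nrow(cand), replace = TRUE)
      want <- ct$distance + g1$delta[m1] + g2$delta[m2]
      dd <- D[cand]
      hit <- which(abs(dd - want) <= 0.15)
      if (!length(hit)) {
        if (min(D[cand]) > ct$distance + max(g1$delta) + max(g2$delta))
          stop("infeasible planted contact: target distance ",
               ct$distance, " A is below the packing minimum")
        next
      }
      hit <- hit[stats::runif(length(hit)) < ct$prob]
      for (p in hit) {
        i <- cand[p, 1]; j <- cand[p, 2]
        if (pinned[i] || pinned[j]) next
        if (stats::runif(1) < 0.5) { aa[i] <- m1[p]; aa[j] <- m2[p] }
        else                       { aa[i] <- m2[p]; aa[j] <- m1[p] }
        pinned[i] <- pinned[j] <- TRUE
        planted[[length(planted) + 1L]] <-
          list(i = i, j = j, region = ct$region, distance = ct$distance,
               d_geom = dd[p], aa_i = aa[i], aa_j = aa[j])
      }
    }
  }

  residues <- data.frame(chain = "A", seq_index = seq_len(n),
                         resno = seq_len(n), aa = aa,
                         x = centers[, 1], y = centers[, 2], z = centers[, 3],
                         region = region, side = side,
                         center_fallback = FALSE, stringsAsFactors = FALSE)
  struct <- structure(list(structure_id = id,
                           topology_class = topology,
                           residues = residues),
                      class = "labeled_structure")
  # annotation records: contiguous runs of equal region label
  r <- rle(region)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("TM", "EM")
  ann <- region_annotation(structure_id = id, chain = "A",
                           start = starts[keep], end = ends[keep],
                           region = r$values[keep],
                           side = ifelse(is.na(side[starts[keep]]), "-",
                                         side[starts[keep]]))
  truth <- list(id = id, topology = topology, n_residues = n,
                n_tm = sum(region == "TM"), n_em = sum(region == "EM"),
                planted = planted,
                separable = !identical(config$comp_TM, config$comp_EM) ||
                  length(config$contacts) > 0)
  list(structure = struct, pdb_lines = write_structure_pdb(struct),
       annotation = ann, truth = truth)
}

resolve_group <- function(g, groups, radii) {
  if (inherits(g, "group_def")) return(g)
  if (is.character(g) && length(g) == 1L && g %in% names(groups))
    return(groups[[g]])
  group_def(paste(g, collapse = "+"), g, radii)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_proteins` PDB files, one annotation TSV and a
#' `truth.json` (compositions, planted contacts, separability flag)
#' into a directory.  Per-protein seeds are derived deterministically
#' from the dataset seed.
#'
#' @param config a `fixture_config`.
#' @param seed dataset seed.
#' @param dir output directory (created if missing).
#' @return invisibly, the list of generated `labeled_structure`
#'   objects.
#' @export
generate_dataset <- function(config, seed, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  gen <- generate_structures(config, seed)
  anns <- list()
  truths <- list()
  for (g in gen) {
    writeLines(g$pdb_lines, file.path(dir, paste0(g$structure$structure_id,
                                                  ".pdb")))
    anns[[length(anns) + 1L]] <- g$annotation
    truths[[length(truths) + 1L]] <- g$truth
  }
  ann <- do.call(rbind, anns)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = seed,
                            separable = truths[[1]]$separable,
                            comp_TM = as.list(config$comp_TM),
                            comp_EM = as.list(config$comp_EM),
                            contacts = config$contacts,
                            proteins = truths),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(lapply(gen, `[[`, "structure"))
}

#' Generate a synthetic dataset in memory
#'
#' @inheritParams generate_dataset
#' @return list of per-structure generation results (see
#'   [generate_structure()]).
#' @export
generate_structures <- function(config, seed) {
  n_alpha <- round(config$n_proteins * config$alpha_fraction)
  lapply(seq_len(config$n_proteins), function(i) {
    topo <- if (i <= n_alpha) "alpha_helical" else "beta_barrel"
    if (config$topology == "beta_barrel") topo <- "beta_barrel"
    generate_structure(config, seed = (seed * 1009L + i) %% .Machine$integer.max,
                       id = sprintf("synth%03d", i), topology = topo)
  })
}

#' Amino-acid composition per region
#'
#' Relative frequencies of the 20 amino acids in each region label
#' present (and optionally per side label).
#'
#' @param structures list of labeled structures.
#' @param by_side split EM residues by side label.
#' @return matrix of relative frequencies, regions (or region:side)
#'   in rows, amino acids in columns; rows sum to 1.
#' @export
region_composition <- function(structures, by_side = FALSE) {
  res <- do.call(rbind, lapply(structures, function(s)
    s$residues[, c("aa", "region", "side")]))
  if (is.null(res)) stop("no region-labeled residues")
  res <- res[res$region %in% c("TM", "EM"), , drop = FALSE]
  if (nrow(res) == 0L) stop("no region-labeled residues")
  key <- if (by_side)
    ifelse(res$region == "EM" & !is.na(res$side),
           paste(res$region, res$side, sep = ":"), res$region)
  else res$region
  tab <- table(factor(key), factor(res$aa, levels = AA3))
  if (any(rowSums(tab) == 0)) stop("empty region")
  sweep(unclass(tab), 1, rowSums(tab), "/")
}
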