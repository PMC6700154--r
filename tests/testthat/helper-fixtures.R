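# in-code fixtures: tiny PDB texts and hand-built labeled structures

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = "", record = "ATOM", elem = NULL) {
  if (is.null(elem)) elem <- substring(gsub("^[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resn, chain, resno, x, y, z, occ, 0,
          elem)
}

# full-backbone + side-chain PDB for a small peptide; coords is a list
# of per-residue named coordinate lists
make_pdb_text <- function(residues) {
  lines <- character(0)
  serial <- 0L
  for (r in residues) {
    for (an in names(r$atoms)) {
      serial <- serial + 1L
      xyz <- r$atoms[[an]]
      lines <- c(lines, pdb_atom_line(serial, an, r$resn,
                                      r$chain %||% "A", r$resno,
                                      xyz[1], xyz[2], xyz[3],
                                      occ = r$occ %||% 1,
                                      alt = r$alt %||% "",
                                      record = r$record %||% "ATOM"))
    }
  }
  c(lines, "END")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gly-Ala-Leu tripeptide with full heavy atoms, ~3.8 A CA spacing
gal_residues <- function(chain = "A", resno0 = 1L) {
  list(
    list(resn = "GLY", chain = chain, resno = resno0,
         atoms = list(N = c(-1.2, 0, 0), CA = c(0, 0, 0), C = c(1.2, 0.6, 0),
                      O = c(1.3, 1.8, 0))),
    list(resn = "ALA", chain = chain, resno = resno0 + 1L,
         atoms = list(N = c(2.4, 0, 0), CA = c(3.8, 0, 0), C = c(5.0, 0.6, 0),
                      O = c(5.1, 1.8, 0), CB = c(3.8, -1.0, 1.0))),
    list(resn = "LEU", chain = chain, resno = resno0 + 2L,
         atoms = list(N = c(6.2, 0, 0), CA = c(7.6, 0, 0), C = c(8.8, 0.6, 0),
                      O = c(8.9, 1.8, 0), CB = c(7.6, -1.2, 0.9),
                      CG = c(7.6, -2.5, 0.2), CD1 = c(8.8, -3.3, 0.5),
                      CD2 = c(6.4, -3.3, 0.5))))
}

# labeled structure straight from vectors (centers given directly)
make_structure <- function(aa, xyz, chain = "A", region = "TM",
                           id = "fix", topology = "alpha_helical") {
  n <- length(aa)
  xyz <- matrix(xyz, ncol = 3)
  chain <- rep_len(chain, n)
  region <- rep_len(region, n)
  seq_index <- stats::ave(seq_len(n), chain, FUN = seq_along)
  res <- data.frame(chain = chain, seq_index = seq_index,
                    resno = seq_index, aa = aa,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    region = region, side = NA_character_,
                    center_fallback = FALSE, stringsAsFactors = FALSE)
  structure(list(structure_id = id, topology_class = topology,
                 residues = res),
            class = "labeled_structure")
}

# random structure with all pair distances inside the binning range
random_structure <- function(n = 50, id = "rand", region = "TM",
                             spread = 6) {
  aa <- sample(mempot:::AA3, n, replace = TRUE)
  xyz <- matrix(stats::runif(3 * n, 0, spread), ncol = 3)
  make_structure(aa, xyz, region = region, id = id)
}

# literal inverse-Boltzmann oracle over a symmetric m x m x 24 array;
# smoothing and guard written independently of the package internals
oracle_smooth <- function(arr, beta = 4, alpha = 4 / 3) {
  out <- arr
  nb <- dim(arr)[3]
  for (d in 1:(nb - 1)) {
    acc <- arr[, , d]
    for (i in 1:beta) {
      if (d - i >= 1) acc <- acc + alpha^(-i) * arr[, , d - i]
      if (d + i <= nb - 1) acc <- acc + alpha^(-i) * arr[, , d + i]
    }
    out[, , d] <- acc
  }
  out
}

oracle_potential_sds <- function(raw, kBT = 0.5925, thr = 10,
                                 on = "raw") {
  sm <- oracle_smooth(raw)
  m <- dim(raw)[1]; nb <- dim(raw)[3]
  n_pair_aa <- apply(sm, c(1, 2), sum)
  n_dist <- apply(sm, 3, sum)
  n_tot <- sum(sm)
  guard <- if (on == "raw") raw else sm
  W <- array(0, dim = dim(raw))
  for (a in 1:m) for (b in 1:m) for (d in 1:nb) {
    if (guard[a, b, d] >= thr && n_pair_aa[a, b] > 0 && n_dist[d] > 0 &&
        sm[a, b, d] > 0)
      W[a, b, d] <- -kBT * log(sm[a, b, d] * n_tot /
                                 (n_pair_aa[a, b] * n_dist[d]))
  }
  W
}

oracle_potential_sd <- function(raw, kBT = 0.5925, thr = 10,
                                on = "raw") {
  sm <- oracle_smooth(raw)
  m <- dim(raw)[1]; nb <- dim(raw)[3]
  n_single <- apply(sm, c(1, 3), sum)
  n_single_raw <- apply(raw, c(1, 3), sum)
  n_single_aa <- apply(sm, 1, sum)
  n_dist <- apply(sm, 3, sum)
  n_tot <- sum(sm)
  guard <- if (on == "raw") n_single_raw else n_single
  W <- matrix(0, m, nb)
  for (a in 1:m) for (d in 1:nb) {
    if (guard[a, d] >= thr && n_single_aa[a] > 0 && n_dist[d] > 0 &&
        n_single[a, d] > 0)
      W[a, d] <- -kBT * log(n_single[a, d] * n_tot /
                              (n_single_aa[a] * n_dist[d]))
  }
  W
}

random_count_array <- function(m = 20, sparse = 0.3) {
  arr <- array(0, dim = c(m, m, 24))
  for (d in 1:24) {
    M <- matrix(stats::rpois(m * m, sample(c(0.2, 3, 30), 1)), m, m)
    M[stats::runif(m * m) < sparse] <- 0
    arr[, , d] <- M + t(M)
  }
  dimnames(arr) <- list(mempot:::AA3[1:m], mempot:::AA3[1:m], NULL)
  arr
}
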