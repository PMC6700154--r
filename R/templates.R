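# Idealized planar side-chain templates (heavy atoms, local frame,
# Angstrom).  Bond lengths and branching are approximate; only the
# overall size matters here — the templates back the shipped radius
# table and the generator's full-atom mode.
sidechain_templates <- function() {
  m <- function(...) {
    v <- list(...)
    out <- do.call(rbind, lapply(v, function(a) c(a[[2]], a[[3]], 0)))
    rownames(out) <- vapply(v, `[[`, "", 1)
    out
  }
  a <- function(name, x, y) list(name, x, y)
  list(
    ALA = m(a("CB", 0, 0)),
    ARG = m(a("CB", 0, 0), a("CG", 1.3, 0.4), a("CD", 2.6, 0),
            a("NE", 3.9, 0.4), a("CZ", 5.2, 0), a("NH1", 6.2, 0.8),
            a("NH2", 6.2, -0.8)),
    ASN = m(a("CB", 0, 0), a("CG", 1.3, 0.4), a("OD1", 2.4, -0.2),
            a("ND2", 1.4, 1.7)),
    ASP = m(a("CB", 0, 0), a("CG", 1.3, 0.4), a("OD1", 2.4, -0.2),
            a("OD2", 1.4, 1.7)),
    CYS = m(a("CB", 0, 0), a("SG", 1.8, 0)),
    GLN = m(a("CB", 0, 0), a("CG", 1.3, 0.4), a("CD", 2.6, 0),
            a("OE1", 3.7, 0.6), a("NE2", 2.7, -1.3)),
    GLU = m(a("CB", 0, 0), a("CG", 1.3, 0.4), a("CD", 2.6, 0),
            a("OE1", 3.7, 0.6), a("OE2", 2.7, -1.3)),
    GLY = m(a("CA", 0, 0))[0, , drop = FALSE],
    HIS = m(a("CB", 0, 0), a("CG", 1.4, 0.3), a("ND1", 2.3, 1.2),
            a("CD2", 2.3, -0.8), a("CE1", 3.5, 0.8),
            a("NE2", 3.5, -0.4)),
    ILE = m(a("CB", 0, 0), a("CG1", 1.25, 0.5), a("CG2", 0.6, -1.4),
            a("CD1", 2.5, 0.9)),
    LEU = m(a("CB", 0, 0), a("CG", 1.3, 0.4), a("CD1", 2.55, 1.0),
            a("CD2", 2.3, -0.9)),
    LYS = m(a("CB", 0, 0), a("CG", 1.3, 0.4), a("CD", 2.6, 0),
            a("CE", 3.9, 0.4), a("NZ", 5.2, 0)),
    MET = m(a("CB", 0, 0), a("CG", 1.3, 0.5), a("SD", 2.7, -0.2),
            a("CE", 4.0, 0.4)),
    PHE = m(a("CB", 0, 0), a("CG", 1.41, 0), a("CD1", 2.1, 1.2),
            a("CD2", 2.1, -1.2), a("CE1", 3.5, 1.2),
            a("CE2", 3.5, -1.2), a("CZ", 4.19, 0)),
    PRO = m(a("CB", 0, 0), a("CG", 1.2, 0.9), a("CD", 2.1, -0.2)),
    SER = m(a("CB", 0, 0), a("OG", 1.4, 0)),
    THR = m(a("CB", 0, 0), a("OG1", 1.2, 0.9), a("CG2", 1.2, -0.9)),
    TRP = m(a("CB", 0, 0), a("CG", 1.4, 0.2), a("CD1", 2.1, 1.3),
            a("NE1", 3.4, 1.2), a("CD2", 2.4, -0.8),
            a("CE2", 3.6, 0), a("CE3", 2.6, -2.2),
            a("CZ2", 4.8, -0.7), a("CZ3", 3.8, -2.9),
            a("CH2", 4.9, -2.1)),
    TYR = m(a("CB", 0, 0), a("CG", 1.41, 0), a("CD1", 2.1, 1.2),
            a("CD2", 2.1, -1.2), a("CE1", 3.5, 1.2),
            a("CE2", 3.5, -1.2), a("CZ", 4.19, 0), a("OH", 5.55, 0)),
    VAL = m(a("CB", 0, 0), a("CG1", 1.25, 0.9), a("CG2", 1.25, -0.9)))
}

template_radius <- function(tpl) {
  if (nrow(tpl) == 0L) return(0)
  ctr <- colMeans(tpl)
  mean(sqrt(rowSums(sweep(tpl, 2, ctr)^2)))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Attach full-atom detail to a labeled structure
#'
#' Places the idealized side-chain template of each residue, randomly
#' rotated and centered on the residue's side-chain geometric center,
#' plus approximate backbone atoms, filling the `atoms` slot used by
#' [estimate_residue_radii()].  Rigid placement preserves each
#' template's radius exactly.
#'
#' @param structure a `labeled_structure`.
#' @param seed integer seed for the rotations.
#' @return the structure with an `atoms` data frame.
#' @export
add_atom_detail <- function(structure, seed = 1L) {
  set.seed(as.integer(seed))
  tpls <- sidechain_templates()
  res <- structure$residues
  rows <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    ctr <- c(res$x[i], res$y[i], res$z[i])
    tpl <- tpls[[res$aa[i]]]
    if (nrow(tpl) == 0L) {                 # Gly: C-alpha at the center
      xyz <- matrix(ctr, 1, 3)
      nm <- "CA"
    } else {
      R <- random_rotation()
      local <- sweep(tpl, 2, colMeans(tpl))
      xyz <- sweep(local %*% t(R), 2, ctr, "+")
      # backbone stubs offset from the side-chain center
      bb <- sweep(matrix(c(-1.5, 0, 2.0,  -1.5, 0, 0.5,
                           -2.8, 0, 0.0,  -3.6, 0, 1.0),
                         4, 3, byrow = TRUE) %*% t(R), 2, ctr, "+")
      xyz <- rbind(bb, xyz)
      nm <- c("N", "CA", "C", "O", rownames(tpl))
    }
    rows[[i]] <- data.frame(chain = res$chain[i], seq_index = res$seq_index[i],
                            resno = res$resno[i], aa = res$aa[i],
                            atom = nm, x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE)
  }
  structure$atoms <- do.call(rbind, rows)
  structure
}
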