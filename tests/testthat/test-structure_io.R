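test_that("a small peptide parses with correct side-chain centers", {
  txt <- make_pdb_text(gal_residues())
  s <- parse_structure(txt, id = "gal")
  expect_s3_class(s, "labeled_structure")
  expect_equal(nrow(s$residues), 3)
  expect_equal(s$residues$seq_index, 1:3)
  expect_equal(s$residues$aa, c("GLY", "ALA", "LEU"))
  # Gly center is its C-alpha
  expect_equal(unlist(s$residues[1, c("x", "y", "z")]),
               c(x = 0, y = 0, z = 0))
  # Ala center is its single C-beta
  expect_equal(unlist(s$residues[2, c("x", "y", "z")]),
               c(x = 3.8, y = -1.0, z = 1.0))
  # Leu center is the mean of CB, CG, CD1, CD2
  leu <- gal_residues()[[3]]$atoms
  ctr <- colMeans(do.call(rbind, leu[c("CB", "CG", "CD1", "CD2")]))
  expect_equal(unlist(s$residues[3, c("x", "y", "z")]),
               c(x = ctr[1], y = ctr[2], z = ctr[3]),
               ignore_attr = TRUE)
  expect_true(all(s$residues$region == "UNASSIGNED"))
})

test_that("selenomethionine maps to Met and other het residues are skipped", {
  res <- gal_residues()
  res[[2]]$resn <- "MSE"
  res[[2]]$record <- "HETATM"
  res[[2]]$atoms <- list(N = c(2.4, 0, 0), CA = c(3.8, 0, 0),
                         C = c(5.0, 0.6, 0), O = c(5.1, 1.8, 0),
                         CB = c(3.8, -1.2, 0.8), CG = c(3.8, -2.5, 0),
                         SE = c(5.2, -3.5, 0.4), CE = c(5.2, -5.0, 0.4))
  res[[4]] <- list(resn = "HOH", chain = "A", resno = 99,
                   record = "HETATM", atoms = list(O = c(20, 20, 20)))
  s <- parse_structure(make_pdb_text(res), id = "mse")
  expect_equal(s$residues$aa, c("GLY", "MET", "LEU"))
  # SE counts as a side-chain heavy atom of the mapped Met
  mse_atoms <- res[[2]]$atoms[c("CB", "CG", "SE", "CE")]
  ctr <- colMeans(do.call(rbind, mse_atoms))
  expect_equal(as.numeric(s$residues[2, c("x", "y", "z")]), as.numeric(ctr),
               tolerance = 1e-6)
})

test_that("chains keep their ids and per-chain numbering restarts", {
  txt <- make_pdb_text(c(gal_residues("A"), gal_residues("B", resno0 = 11L)))
  s <- parse_structure(txt, id = "ab")
  expect_equal(s$residues$chain, rep(c("A", "B"), each = 3))
  expect_equal(s$residues$seq_index, rep(1:3, 2))
  expect_equal(s$residues$resno, c(1:3, 11:13))
})

test_that("altLoc keeps the highest-occupancy conformer, ties to A", {
  res <- gal_residues()
  base <- res[[2]]
  altB <- base
  altB$alt <- "B"; altB$occ <- 0.7
  altB$atoms <- list(CB = c(9, 9, 9))
  altA <- base
  altA$alt <- "A"; altA$occ <- 0.3
  altA$atoms <- list(CB = base$atoms$CB)
  res[[2]]$atoms$CB <- NULL
  txt <- make_pdb_text(list(res[[1]], res[[2]], altA, altB, res[[3]]))
  s <- parse_structure(txt, id = "alt")
  expect_equal(as.numeric(s$residues[2, c("x", "y", "z")]), c(9, 9, 9))

  altB$occ <- 0.3                       # now tied: A wins
  txt <- make_pdb_text(list(res[[1]], res[[2]], altA, altB, res[[3]]))
  s <- parse_structure(txt, id = "alt2")
  expect_equal(as.numeric(s$residues[2, c("x", "y", "z")]),
               as.numeric(base$atoms$CB))
})

test_that("unparseable or empty input errors", {
  expect_error(parse_structure("not a pdb at all\nstill not\n"))
  hoh <- list(list(resn = "HOH", chain = "A", resno = 1, record = "HETATM",
                   atoms = list(O = c(0, 0, 0))))
  expect_error(parse_structure(make_pdb_text(hoh)), "no standard")
})

test_that("side-chain center conventions hold", {
  expect_equal(compute_side_chain_center(
    data.frame(atom = c("N", "CA", "CB"), x = c(9, 5, 1), y = c(9, 5, 2),
               z = c(9, 5, 3)), aa = "ALA"), c(1, 2, 3))
  expect_equal(compute_side_chain_center(
    data.frame(atom = "CA", x = 0, y = 0, z = 0), aa = "GLY"), c(0, 0, 0))
  # symmetric ring about (2, 0, 0)
  th <- 2 * pi * (0:5) / 6
  ring <- data.frame(atom = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                     x = 2 + 1.4 * cos(th), y = 1.4 * sin(th), z = 0)
  expect_equal(compute_side_chain_center(ring, aa = "PHE"), c(2, 0, 0))
  # backbone-only residue falls back to C-alpha and is flagged
  fb <- compute_side_chain_center(
    data.frame(atom = c("N", "CA", "C"), x = 0:2, y = 0, z = 0), aa = "SER")
  expect_equal(as.numeric(fb), c(1, 0, 0))
  expect_true(attr(fb, "fallback"))
  expect_error(compute_side_chain_center(
    data.frame(atom = character(), x = numeric(), y = numeric(),
               z = numeric())))
})

test_that("region assignment applies segments, defaults to EM, checks errors", {
  s <- make_structure(rep("ALA", 40), cbind(seq_len(40) * 3.8, 0, 0),
                      id = "seg", region = "UNASSIGNED")
  ann <- region_annotation("seg", "A", 5, 25, "TM")
  s2 <- assign_regions(s, ann)
  expect_equal(sum(s2$residues$region == "TM"), 21)
  expect_equal(which(s2$residues$region == "TM"), 5:25)
  expect_true(all(s2$residues$region[c(1:4, 26:40)] == "EM"))
  # idempotent and label-conserving
  s3 <- assign_regions(s2, ann)
  expect_identical(s3$residues$region, s2$residues$region)
  expect_equal(sum(s2$residues$region %in% c("TM", "EM")), 40)
  # helical hairpin: two TM segments -> three EM stretches
  ann2 <- region_annotation("seg", "A", c(5, 20), c(12, 30), "TM")
  r <- rle(assign_regions(s, ann2)$residues$region)
  expect_equal(r$values, c("EM", "TM", "EM", "TM", "EM"))
  # strict mode errors on missing annotation
  expect_error(assign_regions(s, region_annotation("other", "A", 1, 5, "TM"),
                              strict = TRUE), "no annotation")
  # overlap and missing chain
  expect_error(region_annotation("seg", "A", c(5, 10), c(15, 20), "TM"),
               "overlapping")
  expect_error(assign_regions(s, region_annotation("seg", "Z", 1, 5, "TM")),
               "missing chain")
})

test_that("PDB round trip preserves side-chain centers", {
  set.seed(42)
  s <- random_structure(30, id = "rt")
  txt <- write_structure_pdb(s)
  s2 <- parse_structure(txt, id = "rt")
  expect_equal(s2$residues$aa, s$residues$aa)
  expect_equal(as.matrix(s2$residues[, c("x", "y", "z")]),
               as.matrix(s$residues[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("annotation TSV round-trips through the reader", {
  ann <- region_annotation(c("p1", "p1", "p2"), c("A", "A", "B"),
                           c(3, 30, 1), c(25, 55, 10),
                           c("TM", "EM", "TM"), c("-", "in", "-"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_region_annotation(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
})

test_that("residue radii recover the template geometry", {
  set.seed(7)
  st <- lapply(1:3, function(i)
    add_atom_detail(random_structure(60, id = paste0("r", i)), seed = i))
  r <- estimate_residue_radii(st)
  # rigid placement preserves each template's radius exactly
  expect_equal(r, default_residue_radii(), tolerance = 1e-9)
  expect_equal(unname(r["GLY"]), 0)
  expect_equal(unname(r["ALA"]), 0)
  expect_gt(r["TRP"], r["ALA"])
  expect_error(estimate_residue_radii(list()), "empty")
})

test_that("a hand-built symmetric ring gives its hand-computed radius", {
  # six ring atoms at 1.4 A from their centroid
  th <- 2 * pi * (0:5) / 6
  atoms <- data.frame(chain = "A", seq_index = 1, resno = 1, aa = "PHE",
                      atom = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      x = 1.4 * cos(th), y = 1.4 * sin(th), z = 5,
                      stringsAsFactors = FALSE)
  s <- make_structure("PHE", c(0, 0, 5), id = "ring")
  s$atoms <- atoms
  r <- estimate_residue_radii(list(s))
  expect_equal(unname(r["PHE"]), 1.4, tolerance = 1e-9)
})
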