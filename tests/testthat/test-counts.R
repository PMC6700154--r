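test_that("distances map to the stated bins", {
  expect_equal(distance_to_bin(3.0), 1L)          # lower edge
  expect_equal(distance_to_bin(9.95), 24L)        # overflow
  expect_equal(distance_to_bin(4.05), 4L)         # floor((4.05-3)/0.3) = 3
  expect_equal(distance_to_bin(c(3.29, 3.3, 9.89, 9.9)),
               c(1L, 2L, 23L, 24L))
  expect_equal(distance_to_bin(2.5), 1L)          # clamp policy
  expect_true(is.na(distance_to_bin(2.5, binning_scheme("discard"))))
  expect_error(distance_to_bin(-1))
  expect_error(distance_to_bin(NaN))
  sc <- binning_scheme()
  expect_equal(sc$edges, 3.0 + 0.3 * (0:23))
  expect_equal(sc$n_bins, 24L)
})

test_that("adjacency and region rules control pair eligibility", {
  s <- make_structure(c("ALA", "GLY", "LEU"),
                      c(0, 2, 4, 0, 0, 0, 0, 0, 0), id = "tri")
  pc <- accumulate_pair_counts(list(s), "TM")
  # only (1,3) is eligible: |i-j| > 1; total = 2 under double storage
  expect_equal(sum(pc$n_pair), 2)
  i <- mempot:::aa_index(c("ALA", "LEU"))
  expect_equal(pc$n_pair[i[1], i[2], distance_to_bin(4)], 1)
  expect_equal(pc$n_pair[i[2], i[1], distance_to_bin(4)], 1)

  s2 <- make_structure(c("ALA", "GLY", "LEU"), c(0, 2, 4, 0, 0, 0, 0, 0, 0),
                       region = c("TM", "TM", "EM"), id = "cross")
  expect_equal(sum(accumulate_pair_counts(list(s2), "TM")$n_pair), 0)

  s3 <- s
  s3$residues$region <- "UNASSIGNED"
  expect_error(accumulate_pair_counts(list(s3), "TM"), "unassigned")
  expect_error(accumulate_pair_counts(list(), "TM"), "empty")
})

test_that("pooled counts equal an independent all-pairs recount", {
  set.seed(101)
  st <- lapply(1:3, function(i) random_structure(60, id = paste0("bf", i)))
  pc <- accumulate_pair_counts(st, "TM")
  ref <- array(0, dim = c(20, 20, 24))
  n_events <- 0
  for (s in st) {
    r <- s$residues
    for (i in seq_len(nrow(r) - 2)) for (j in (i + 2):nrow(r)) {
      d <- sqrt(sum((r[i, c("x", "y", "z")] - r[j, c("x", "y", "z")])^2))
      b <- distance_to_bin(d)
      a1 <- mempot:::aa_index(r$aa[i]); a2 <- mempot:::aa_index(r$aa[j])
      ref[a1, a2, b] <- ref[a1, a2, b] + 1
      ref[a2, a1, b] <- ref[a2, a1, b] + 1
      n_events <- n_events + 1
    }
  }
  expect_equal(unname(pc$n_pair), ref)
  expect_equal(sum(pc$n_pair), 2 * n_events)   # double-storage conservation
  # marginals are sums of the table
  mg <- mempot:::counts_marginals(pc)
  expect_equal(mg$n_total, sum(pc$n_pair))
  expect_equal(mg$n_dist, apply(pc$n_pair, 3, sum))
})

test_that("per-protein sub-counts add up and support exact LOO subtraction", {
  set.seed(11)
  st <- lapply(1:4, function(i) random_structure(40, id = paste0("p", i)))
  pc <- accumulate_pair_counts(st, "TM")
  expect_equal(Reduce(`+`, pc$per_protein), unname(pc$n_pair),
               ignore_attr = TRUE)
  red <- subtract_protein_counts(pc, "p2")
  rebuilt <- accumulate_pair_counts(st[-2], "TM")
  expect_equal(red$n_pair, rebuilt$n_pair)
  expect_error(subtract_protein_counts(pc, "nope"), "unknown")
})

test_that("smoothing matches the literal kernel and spares the overflow bin", {
  for (j in c(1L, 3L, 12L, 23L)) {
    arr <- array(0, dim = c(20, 20, 24))
    arr[1, 2, j] <- arr[2, 1, j] <- 1
    sm <- smooth_counts(pair_counts(arr))
    got <- sm$n_pair[1, 2, ]
    want <- numeric(24)
    for (k in 1:23) if (abs(k - j) <= 4) want[k] <- (3 / 4)^abs(k - j)
    expect_equal(got, want, info = paste("impulse at bin", j))
    expect_equal(sm$n_pair[1, 2, 24], 0)   # overflow untouched as recipient
  }
  # overflow impulse stays put: excluded as source
  arr <- array(0, dim = c(20, 20, 24))
  arr[1, 1, 24] <- 2
  sm <- smooth_counts(pair_counts(arr))
  expect_equal(sm$n_pair[1, 1, ], c(rep(0, 23), 2))
  # all-zero in, all-zero out; double smoothing refused
  z <- smooth_counts(pair_counts(array(0, dim = c(20, 20, 24))))
  expect_true(all(z$n_pair == 0))
  expect_error(smooth_counts(z), "already")
})

test_that("smoothing is linear and matches the 9-term oracle on random tables", {
  set.seed(5)
  X <- random_count_array()
  Y <- random_count_array()
  sX <- smooth_counts(pair_counts(X))$n_pair
  sY <- smooth_counts(pair_counts(Y))$n_pair
  sXY <- smooth_counts(pair_counts(2 * X + 3 * Y))$n_pair
  expect_equal(sXY, 2 * sX + 3 * sY, tolerance = 1e-12)
  expect_equal(sX, oracle_smooth(X), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group pooling shifts distances by radius differences", {
  radii <- c(default_residue_radii())
  radii[c("LYS", "ARG", "ASP", "GLU")] <- c(1.7, 2.0, 1.0, 1.4)
  pos <- group_def("positive", c("LYS", "ARG"), radii)
  neg <- group_def("negative", c("GLU", "ASP"), radii)
  expect_equal(unname(pos$delta), c(0, 0.3))
  expect_equal(unname(neg$delta), c(0.4, 0))
  # single Lys-Asp pair at 4.6 with delta(Lys) = 0.3 after re-basing
  radii2 <- radii; radii2["LYS"] <- 2.3   # now Lys is the larger member
  pos2 <- group_def("positive", c("LYS", "ARG"), radii2)
  expect_equal(unname(pos2$delta["LYS"]), 0.3)
  s <- make_structure(c("LYS", "GLY", "ASP"),
                      c(0, 50, 4.6, 0, 50, 0, 0, 50, 0), id = "kd")
  pc <- pool_group_counts(list(s), "TM", pos2, neg)
  expect_equal(sum(pc$n_pair), 1)
  expect_equal(which(pc$n_pair[1, 1, ] > 0), distance_to_bin(4.3))

  # all shifts zero: pooled table equals the sum of member-pair cells
  radii0 <- radii; radii0[c("LYS", "ARG")] <- 2; radii0[c("GLU", "ASP")] <- 1
  pos0 <- group_def("positive", c("LYS", "ARG"), radii0)
  neg0 <- group_def("negative", c("GLU", "ASP"), radii0)
  set.seed(3)
  st <- lapply(1:2, function(i) random_structure(50, id = paste0("g", i)))
  gp <- pool_group_counts(st, "TM", pos0, neg0)
  full <- accumulate_pair_counts(st, "TM")
  block <- mempot:::aa_index(c("LYS", "ARG"))
  blockn <- mempot:::aa_index(c("GLU", "ASP"))
  want <- apply(full$n_pair[block, blockn, , drop = FALSE], 3, sum)
  expect_equal(gp$n_pair[1, 1, ], want)

  # self-pair group: one Arg-Arg pair gives one symmetric (doubled) event
  sr <- make_structure(c("ARG", "GLY", "ARG"),
                       c(0, 50, 5, 0, 50, 0, 0, 50, 0), id = "rr")
  gpp <- pool_group_counts(list(sr), "TM", pos0, pos0)
  expect_equal(sum(gpp$n_pair), 2)
  expect_error(pool_group_counts(list(sr), "TM", pos0,
                                 group_def("mix", c("ARG", "GLU"), radii0)),
               "disjoint")
})

test_that("counts serialize to TSV and back", {
  set.seed(9)
  pc <- accumulate_pair_counts(list(random_structure(40, id = "ser")), "TM")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(pc, path)
  back <- read_counts_tsv(path)
  expect_equal(back$n_pair, pc$n_pair)
  expect_equal(back$region, "TM")
})
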