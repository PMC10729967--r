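test_that("strand axes are oriented N-to-C and match the builder", {
  pts <- cbind(0:5, 0, 0)
  expect_equal(strand_axis(pts), c(1, 0, 0))
  expect_equal(strand_axis(pts[6:1, ]), c(-1, 0, 0))
  st <- ideal_strand(seq_6k)
  ax <- strand_axis(st$coords[st$beads$kind == "CA", ])
  expect_equal(acos(min(1, abs(sum(ax * c(0, 1, 0))))), 0, tolerance = 1e-6)
  expect_error(strand_axis(pts[1:2, ]), "at least 3")
})

test_that("pair twist is signed, antiparallel-aware and chirality-sensitive", {
  expect_equal(pair_twist(c(0, 1, 0), c(0, 1, 0), c(1, 0, 0)), 0)
  a <- c(0, 1, 0)
  th <- -2.22 * pi / 180
  b <- c(0, cos(th), sin(th))
  expect_equal(pair_twist(a, b, c(1, 0, 0)), -2.22, tolerance = 1e-9)
  # antiparallel neighbour: flipping b should not change the answer
  expect_equal(pair_twist(a, -b, c(1, 0, 0)), -2.22, tolerance = 1e-9)
  # mirror reflection flips the sign
  bm <- b * c(1, 1, -1)
  expect_equal(pair_twist(a, bm, c(1, 0, 0)), 2.22, tolerance = 1e-9)
  expect_error(pair_twist(c(0, 0, 0), b, c(1, 0, 0)), "zero")

  m <- build_sheet(seq_6k, seq_6e, n_strands = 12, twist_per_strand = -2.22)
  expect_equal(sheet_twist(m), -2.22, tolerance = 0.05 / 2.22)
})

test_that("plane fits and sheet separations are exact and isometry-invariant", {
  set.seed(31)
  a <- cbind(runif(30, 0, 20), runif(30, 0, 20), 0)
  b <- cbind(runif(30, 0, 20), runif(30, 0, 20), 11.5)
  # centre the x-y scatter so the centroid offset is purely vertical
  a[, 1:2] <- sweep(a[, 1:2], 2, colMeans(a[, 1:2]), "-")
  b[, 1:2] <- sweep(b[, 1:2], 2, colMeans(b[, 1:2]), "-")
  expect_equal(sheet_separation(a, b), 11.5, tolerance = 1e-12)
  pl <- fit_plane(a)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  # rigid rotation + translation leaves the separation unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot2 <- matrix(c(1, 0, 0, 0, cos(1.1), sin(1.1), 0, -sin(1.1), cos(1.1)), 3, 3)
  rr <- rot %*% rot2
  shift <- c(3, -7, 2)
  expect_equal(sheet_separation(sweep(a %*% t(rr), 2, shift, "+"),
                                sweep(b %*% t(rr), 2, shift, "+")),
               11.5, tolerance = 1e-9)
  expect_error(fit_plane(cbind(0:5, 0, 0)), "collinear")
})

test_that("hydrogen-bond and salt-bridge detectors honour the cutoffs", {
  fx <- salt_bridge_fixture(2.9, 170)
  expect_equal(salt_bridges(fx)$n, 1)
  expect_equal(salt_bridges(fx)$mean_length, 2.9, tolerance = 1e-9)
  expect_equal(salt_bridges(fx)$mean_angle, 170, tolerance = 1e-9)
  expect_equal(salt_bridges(salt_bridge_fixture(2.9, 130))$n, 0)
  expect_equal(salt_bridges(salt_bridge_fixture(3.05, 156))$n, 0)
  sb <- salt_bridges(salt_bridge_fixture(2.8, 156))
  expect_equal(sb$n, 1)
  expect_equal(sb$mean_length, 2.8, tolerance = 1e-9)
  expect_equal(sb$mean_angle, 156, tolerance = 1e-9)
  expect_equal(salt_bridges(salt_bridge_fixture(2.8, 156, acceptor = "D"))$n, 1)
  expect_error(salt_bridge_fixture(-1, 156), "positive")
  expect_error(salt_bridge_fixture(2.8, 200), "angle")

  # lysine facing lysine offers no acceptor
  fx2 <- as.data.frame(salt_bridge_fixture(2.8, 156))
  fx2$code[fx2$chain == "B"] <- "K"
  fx2$atom[fx2$chain == "B"] <- c("CE", "CD", "CB")   # carbons only
  expect_equal(salt_bridges(atomistic_structure(fx2))$n, 0)

  # a donor whose hydrogens are missing is an explicit error
  fx3 <- as.data.frame(fx)
  fx3 <- fx3[fx3$atom != "HZ2", ]
  err <- tryCatch(salt_bridges(atomistic_structure(fx3)),
                  error = conditionMessage)
  expect_match(err, "HZ2")
})

test_that("detectors equal exhaustive oracles on random micro-structures", {
  donors <- data.frame(code = "K", heavy = "NZ", h = c("HZ1", "HZ2", "HZ3"),
                       stringsAsFactors = FALSE)
  acceptors <- data.frame(code = c("D", "D", "E", "E"),
                          atom = c("OD1", "OD2", "OE1", "OE2"),
                          stringsAsFactors = FALSE)
  set.seed(77)
  for (k in 1:50) {
    s <- random_polar_structure(n_res = sample(4:10, 1), span = 10)
    hb <- hydrogen_bonds(s, 3.0, 135, donors, acceptors)
    expect_equal(nrow(hb), oracle_hbonds(s, 3.0, 135, donors, acceptors))
    if (nrow(hb) > 0) {
      expect_true(all(hb$distance <= 3.0 & hb$angle >= 135))
    }
    cm <- contact_map(s, cutoff = 5)
    expect_equal(unclass(cm), oracle_contact_map(s, 5), ignore_attr = TRUE)
    expect_true(isSymmetric(unclass(cm)))
  }
})

test_that("contact counting respects the cutoff, exclusions and selections", {
  s <- atomistic_structure(data.frame(
    chain = c("A", "B", "C"), resno = c(1L, 1L, 1L), code = c("Q", "Q", "F"),
    atom = c("CB", "CB", "CB"), elem = "C",
    x = c(0, 6.9, 7.1), y = 0, z = 0, stringsAsFactors = FALSE))
  cm <- contact_map(s[1:2, ], cutoff = 7)
  expect_equal(cm["Q", "Q"], 1L, ignore_attr = TRUE)
  cm2 <- contact_map(s[c(1, 3), ], cutoff = 7)
  expect_equal(cm2["Q", "F"], 0L, ignore_attr = TRUE)
  expect_equal(group_contacts(s, 1, 2:3, cutoff = 7), 1L)
  expect_error(group_contacts(s, 1:2, 2:3), "disjoint")
  expect_error(group_contacts(s, integer(0), 1:2), "empty")
  # intra-residue pairs are excluded by default but can be counted
  s2 <- atomistic_structure(data.frame(
    chain = "A", resno = 1L, code = "Q", atom = c("CB", "CG"), elem = "C",
    x = c(0, 1.5), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_equal(sum(contact_map(s2, 7)), 0)
  expect_equal(sum(contact_map(s2, 7, exclude_intra = FALSE)), 1)
})

test_that("Kabsch RMSD removes isometries and matches an independent fit", {
  set.seed(41)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
  th <- 1.2
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- sweep(a %*% t(rot), 2, c(5, -2, 1), "+")
  expect_equal(kabsch_rmsd(a, b), 0, tolerance = 1e-9)
  # randomized cross-check against bio3d's superposition
  for (k in 1:10) {
    a <- matrix(rnorm(24), 8, 3)
    b <- a + matrix(rnorm(24, sd = 0.3), 8, 3)
    ours <- kabsch_rmsd(a, b)
    fitted <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(a)), mobile = as.vector(t(b))))
    ref <- sqrt(mean(colSums(matrix((fitted - as.vector(t(a)))^2, nrow = 3))))
    expect_equal(ours, ref, tolerance = 1e-6)
  }
  expect_error(kabsch_rmsd(a, a[1:5, ]), "length")
})

test_that("secondary-structure aggregation conserves occupancy", {
  classes <- c("helix_310", "helix_alpha", "helix_pi", "bend", "turn",
               "coil", "strand")
  set.seed(51)
  asn <- matrix(sample(classes, 40 * 11, replace = TRUE), 40, 11)
  sc <- aggregate_secondary(asn)
  expect_equal(rowSums(sc$per_residue), rep(1, 11), ignore_attr = TRUE)
  expect_equal(sum(sc$per_residue), 11)
  expect_equal(sc$totals[["helix"]],
               sum(sc$totals[c("helix_310", "helix_alpha", "helix_pi")]))
  all_coil <- matrix("coil", 5, 11)
  sc2 <- aggregate_secondary(all_coil)
  expect_equal(sc2$per_residue[, "coil"], rep(1, 11), ignore_attr = TRUE)
  expect_equal(sc2$totals[["coil"]], 11)
  expect_error(aggregate_secondary(matrix("wiggle", 2, 3)), "unknown")
})

test_that("published per-residue monomer table sums to its printed totals", {
  tab <- catch_monomer_secondary()
  tot <- function(pep, col) sum(tab[tab$peptide == pep, col])
  # the self-consistent printed columns
  expect_equal(tot("6K", "helix"), 4.42, tolerance = 1e-9)
  expect_equal(tot("6D", "helix"), 5.24, tolerance = 1e-9)
  expect_equal(tot("6K", "bend"), 1.25, tolerance = 1e-9)
  expect_equal(tot("6E", "bend"), 0.43, tolerance = 1e-9)
  expect_equal(tot("6K", "turn"), 2.88, tolerance = 1e-9)
  expect_equal(tot("6E", "turn"), 2.66, tolerance = 1e-9)
  # class_totals reproduces plain column sums on a combined table
  sub <- tab[tab$peptide == "6K", c("helix", "bend", "turn", "coil")]
  ct <- class_totals(sub)
  expect_equal(ct[["helix"]], 4.42)
  expect_equal(ct[["turn"]], 2.88)
})

test_that("twist, separation and contacts are invariant under isometry", {
  m <- build_sheet(seq_6k, seq_6e, n_strands = 6, twist_per_strand = -3.55)
  cas <- strand_ca_coords(m)
  th <- 0.9
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- lapply(cas, function(x) sweep(x %*% t(rot), 2, c(10, 4, -6), "+"))
  expect_equal(sheet_twist(moved), sheet_twist(cas), tolerance = 1e-9)
  s <- random_polar_structure(6, seed = 91)
  s2 <- s
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(rot)
  s2$x <- xyz[, 1] + 3; s2$y <- xyz[, 2] - 1; s2$z <- xyz[, 3] + 9
  expect_identical(sum(contact_map(s, 5)), sum(contact_map(s2, 5)))
})
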