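test_that("ideal strands have extended geometry with alternating pleat", {
  st <- ideal_strand(seq_6k)
  expect_equal(nrow(st$coords), 44)
  ca <- st$coords[st$beads$kind == "CA", ]
  expect_equal(dist_between(ca[1, ], ca[11, ]), 35, tolerance = 1e-12)
  # consecutive sidechain offsets point to opposite sides of the strand axis
  ridx <- which(st$beads$kind == "R")
  caidx <- which(st$beads$kind == "CA")
  offs <- st$coords[ridx, ] - st$coords[caidx, ]
  dots <- rowSums(offs[-1, ] * offs[-nrow(offs), ])
  expect_true(all(dots < 0))
  # every bond and pseudobond is satisfied exactly
  b <- st$topology$bonds
  r <- sqrt(rowSums((st$coords[b$j, ] - st$coords[b$i, ])^2))
  expect_equal(r, b$length, tolerance = 1e-12)

  bb <- ideal_strand(seq_6k, representation = "backbone_atomistic")
  expect_equal(nrow(bb$coords), 33)
  expect_setequal(unique(bb$beads$kind), c("N", "CA", "C"))
  expect_error(ideal_strand(seq_6k, representation = "all_atom"))
})

test_that("sheets are evenly spaced, charge-alternating and twist-true", {
  m <- build_sheet(seq_6k, seq_6e, n_strands = 12, strand_spacing = 5)
  expect_equal(length(m$strands), 12)
  cas <- strand_ca_coords(m)
  ctr <- t(vapply(cas, colMeans, numeric(3)))
  gaps <- sqrt(rowSums((ctr[-1, ] - ctr[-12, ])^2))
  expect_equal(gaps, rep(5, 11), tolerance = 1e-12)
  # flat sheet: all strand axes parallel
  axes <- lapply(cas, strand_axis)
  for (k in 1:11) {
    expect_equal(abs(sum(axes[[k]] * axes[[k + 1]])), 1, tolerance = 1e-12)
  }
  expect_equal(sheet_twist(m), 0, tolerance = 1e-12)
  # adjacent strands alternate charge sign and orientation
  charges <- vapply(m$strands, `[[`, numeric(1), "net_charge")
  expect_true(all(charges[-1] * charges[-12] < 0))
  oris <- vapply(m$strands, `[[`, character(1), "orientation")
  expect_true(all(oris[-1] != oris[-12]))
  expect_error(build_sheet(seq_6k, seq_6e, n_strands = 1), "n_strands")
  expect_error(build_sheet(seq_6k, seq_6e, strand_spacing = -1), "spacing")
})

test_that("builder twist and spacing are recovered by the metrics (closure)", {
  for (tw in c(-10, -3.55, -2.22, 0.8, 10)) {
    for (sp in c(4, 5, 6)) {
      m <- build_sheet(seq_6k, seq_6e, n_strands = 6, strand_spacing = sp,
                       twist_per_strand = tw)
      expect_equal(sheet_twist(m), tw, tolerance = 0.05 / max(abs(tw), 1))
      expect_equal(sheet_spacing(m), sp, tolerance = 0.01 / sp)
    }
  }
})

test_that("bilayers bury phenylalanine and separate by the requested gap", {
  m <- build_bilayer(seq_6k, seq_6e, sheet_gap = 13)
  expect_equal(length(m$strands), 24)
  charges <- vapply(m$strands, `[[`, numeric(1), "net_charge")
  expect_equal(sum(charges > 0), 12)
  expect_equal(sum(charges < 0), 12)
  expect_equal(sheet_separation(sheet_backbone_coords(m, 1),
                                sheet_backbone_coords(m, 2)),
               13, tolerance = 1e-12)
  # F sidechains of both sheets point into the gap
  beads <- sheet_model_beads(m)
  f1 <- beads[beads$sheet == 1 & beads$kind == "R" & beads$code == "F", "z"]
  f2 <- beads[beads$sheet == 2 & beads$kind == "R" & beads$code == "F", "z"]
  expect_true(all(f1 > 0) && all(f1 < 13))
  expect_true(all(f2 < 13) && all(f2 > 0))
  expect_error(build_bilayer(seq_6k, seq_6e, sheet_gap = -2), "gap")
})

test_that("stacked and separated double bilayers match the printed distances", {
  ke <- build_two_bilayers(seq_6k, seq_6e, "stacked")
  kd <- build_two_bilayers(seq_6k, seq_6d, "stacked")
  d_ke <- sheet_separation(sheet_backbone_coords(ke, 2),
                           sheet_backbone_coords(ke, 3))
  d_kd <- sheet_separation(sheet_backbone_coords(kd, 2),
                           sheet_backbone_coords(kd, 3))
  expect_equal(d_ke, 14.8, tolerance = 1e-9)
  expect_equal(d_kd, 12.7, tolerance = 1e-9)
  # charged sidechains of sheets 2 and 3 face each other across the gap
  beads <- sheet_model_beads(ke)
  k2 <- beads[beads$sheet == 2 & beads$kind == "R" &
                beads$code %in% c("K", "E"), ]
  bb2 <- mean(beads[beads$sheet == 2 & beads$kind != "R", "z"])
  expect_true(mean(k2$z) > bb2)   # pointing up, toward sheet 3
  sep <- build_two_bilayers(seq_6k, seq_6e, "separated")
  d_sep <- sheet_separation(sheet_backbone_coords(sep, 2),
                            sheet_backbone_coords(sep, 3))
  expect_equal(d_sep - d_ke, 10, tolerance = 1e-9)
  expect_error(build_two_bilayers(seq_6k, seq_6e, "sideways"))
})

test_that("random-coil boxes are reproducible, separated and thermalised", {
  s1 <- random_coil_box(seq_6k, seq_6e, 4, 4, 120, min_separation = 5, seed = 7)
  s2 <- random_coil_box(seq_6k, seq_6e, 4, 4, 120, min_separation = 5, seed = 7)
  expect_identical(s1$pos, s2$pos)
  expect_identical(s1$vel, s2$vel)
  s3 <- random_coil_box(seq_6k, seq_6e, 4, 4, 120, min_separation = 5, seed = 8)
  expect_false(identical(s1$pos, s3$pos))

  # inter-peptide minimum-image separation respected
  mind <- Inf
  for (p in 1:7) for (q in (p + 1):8) {
    pi_ <- s1$pos[s1$beads$peptide == p, ]
    qi <- s1$pos[s1$beads$peptide == q, ]
    for (k in seq_len(nrow(pi_))) {
      d <- sweep(qi, 2, pi_[k, ], "-")
      d <- d - 120 * round(d / 120)
      mind <- min(mind, sqrt(min(rowSums(d^2))))
    }
  }
  expect_gte(mind, 5)

  # equipartition: mean kinetic energy per degree of freedom ~ T*/2
  ke <- sum(0.5 * s1$beads$mass * rowSums(s1$vel^2))
  expect_equal(ke / (3 * nrow(s1$pos)), 0.18 / 2, tolerance = 0.1)

  # the state satisfies the engine invariants
  expect_silent(validate_state(s1, default_table))

  expect_error(random_coil_box(seq_6k, seq_6e, 40, 40, 40, seed = 1,
                               max_tries = 3),
               "packing failed")
})

test_that("random-coil conformations keep every bond wall satisfied", {
  set.seed(5)
  for (rep in 1:3) {
    cf <- random_coil_conformation(seq_6e, default_table)
    b <- cf$topology$bonds
    r <- sqrt(rowSums((cf$coords[b$j, ] - cf$coords[b$i, ])^2))
    expect_true(all(r > b$length * (1 - b$delta) - 1e-9))
    expect_true(all(r < b$length * (1 + b$delta) + 1e-9))
  }
  # and genuinely deviate from the extended template
  st <- ideal_strand(seq_6e)
  expect_gt(kabsch_rmsd(cf$coords, st$coords), 1)
})
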