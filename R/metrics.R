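#' Minimal atomistic structure container
#'
#' A plain data frame with one row per atom and columns `chain`, `resno`,
#' `code` (one-letter residue code), `atom` (atom name), `elem`, `x`, `y`,
#' `z`, used by the geometric detectors.  Atom names must be unique within a
#' residue and coordinates finite.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame, classed `atomistic_structure`.
#' @export
atomistic_structure <- function(df) {
  need <- c("chain", "resno", "code", "atom", "elem", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite coordinates")
  }
  key <- paste(df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a residue: ", key[duplicated(key)][1])
  }
  class(df) <- c("atomistic_structure", "data.frame")
  df
}

#' Best-fit strand axis through ordered C-alpha positions
#'
#' Total-least-squares 3-D line through the points (first principal
#' component), sign-oriented from the N-terminal toward the C-terminal
#' C-alpha.
#'
#' @param calpha Matrix of C-alpha coordinates in N-to-C order (>= 3 rows).
#' @return Oriented unit 3-vector.
#' @export
strand_axis <- function(calpha) {
  calpha <- as.matrix(calpha)
  if (nrow(calpha) < 3) stop("need at least 3 C-alpha positions")
  ctr <- colMeans(calpha)
  sv <- svd(sweep(calpha, 2, ctr, "-"))
  if (sv$d[1] < 1e-10) stop("degenerate C-alpha set: no well-defined axis")
  ax <- sv$v[, 1]
  if (sum(ax * (calpha[nrow(calpha), ] - calpha[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Signed twist angle between two neighbouring strand axes
#'
#' Antiparallel neighbours are aligned first (axis_j is flipped when the two
#' axes point oppositely).  The magnitude is the angle between the aligned
#' axes; the sign is that of `(axis_i x axis_j) . stacking`, where `stacking`
#' is the intra-sheet strand-stacking direction from strand i toward strand j
#' (the fibril axis).  Negative values are left-handed.
#'
#' @param axis_i,axis_j Unit axis vectors.
#' @param stacking Strand-stacking direction from i to j.
#' @return Signed angle in degrees.
#' @export
pair_twist <- function(axis_i, axis_j, stacking) {
  ni <- sqrt(sum(axis_i^2)); nj <- sqrt(sum(axis_j^2)); ns <- sqrt(sum(stacking^2))
  if (ni < 1e-12 || nj < 1e-12 || ns < 1e-12) stop("zero vector")
  a <- axis_i / ni; b <- axis_j / nj; s <- stacking / ns
  if (sum(a * b) < 0) b <- -b
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  ang <- acos(max(-1, min(1, sum(a * b)))) * 180 / pi
  ang * sign(sum(cr * s) + (sum(cr * s) == 0))
}

#' Mean signed twist of a sheet
#'
#' Mean of [pair_twist()] over adjacent strand pairs within each sheet.
#'
#' @param x A `sheet_model`, or a list of per-strand C-alpha coordinate
#'   matrices ordered along the sheet.
#' @return Mean signed twist in degrees.
#' @export
sheet_twist <- function(x) {
  if (inherits(x, "sheet_model")) {
    cas <- strand_ca_coords(x)
    groups <- x$sheets
  } else {
    cas <- x
    groups <- list(seq_along(x))
  }
  vals <- c()
  for (g in groups) {
    if (length(g) < 2) next
    axes <- lapply(cas[g], strand_axis)
    ctrs <- lapply(cas[g], colMeans)
    for (k in seq_len(length(g) - 1)) {
      stack <- ctrs[[k + 1]] - ctrs[[k]]
      vals <- c(vals, pair_twist(axes[[k]], axes[[k + 1]], stack))
    }
  }
  if (length(vals) == 0) stop("need at least 2 strands")
  mean(vals)
}

#' Mean spacing between adjacent strands of a sheet
#'
#' Mean Euclidean distance between centroids of adjacent strands (the
#' builder's strand-spacing parameter on noiseless builds).
#'
#' @inheritParams sheet_twist
#' @export
sheet_spacing <- function(x) {
  if (inherits(x, "sheet_model")) {
    cas <- strand_ca_coords(x)
    groups <- x$sheets
  } else {
    cas <- x
    groups <- list(seq_along(x))
  }
  vals <- c()
  for (g in groups) {
    ctrs <- t(vapply(cas[g], colMeans, numeric(3)))
    if (nrow(ctrs) < 2) next
    vals <- c(vals, sqrt(rowSums((ctrs[-1, , drop = FALSE] -
                                    ctrs[-nrow(ctrs), , drop = FALSE])^2)))
  }
  mean(vals)
}

#' Total-least-squares plane fit
#'
#' @param points Matrix of >= 3 non-collinear points.
#' @return List `centroid`, `normal` (unit vector).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr, "-"))
  if (sv$d[2] < 1e-10) stop("degenerate (collinear) point set")
  list(centroid = ctr, normal = sv$v[, 3] / sqrt(sum(sv$v[, 3]^2)))
}

#' Inter-sheet distance from plane fits
#'
#' Fits a plane to the backbone points of each sheet and returns the
#' Euclidean distance between the two plane centroids.
#'
#' @param backbone_a,backbone_b Backbone coordinate matrices of the two
#'   sheets.
#' @return Distance in Angstrom.
#' @export
sheet_separation <- function(backbone_a, backbone_b) {
  pa <- fit_plane(backbone_a)
  pb <- fit_plane(backbone_b)
  sqrt(sum((pa$centroid - pb$centroid)^2))
}

dist_xyz <- function(p, q) sqrt(sum((p - q)^2))

#' Geometric hydrogen-bond detection
#'
#' Finds all (hydrogen, acceptor) pairs with H...A distance at most
#' `distance_cutoff` and donor-H...A angle at least `angle_cutoff` degrees.
#' Donors are given as (residue code, heavy atom, hydrogen atom) triples and
#' acceptors as (residue code, atom) pairs; hydrogens must be present
#' explicitly (a donor residue lacking its named hydrogen is an error, no
#' silent inference).
#'
#' @param structure An `atomistic_structure`.
#' @param distance_cutoff H...acceptor cutoff (Angstrom, default 3.0).
#' @param angle_cutoff Donor-H...acceptor angle cutoff (degrees, default 135).
#' @param donors Data frame `code`, `heavy`, `h`.
#' @param acceptors Data frame `code`, `atom`.
#' @param exclude_same_residue Drop donor/acceptor pairs within one residue.
#' @return Data frame of bonds: donor chain/resno, acceptor chain/resno,
#'   atom names, `distance`, `angle`.
#' @export
hydrogen_bonds <- function(structure, distance_cutoff = 3.0, angle_cutoff = 135,
                           donors, acceptors, exclude_same_residue = TRUE) {
  don <- list(); acc <- list()
  for (k in seq_len(nrow(donors))) {
    res <- structure[structure$code == donors$code[k], , drop = FALSE]
    for (rk in unique(paste(res$chain, res$resno))) {
      sub <- res[paste(res$chain, res$resno) == rk, , drop = FALSE]
      hrow <- sub[sub$atom == donors$h[k], , drop = FALSE]
      drow <- sub[sub$atom == donors$heavy[k], , drop = FALSE]
      if (nrow(drow) == 1 && nrow(hrow) == 0) {
        stop(sprintf("missing hydrogen %s on donor residue %s %s%s",
                     donors$h[k], donors$code[k], sub$chain[1], sub$resno[1]))
      }
      if (nrow(hrow) == 1 && nrow(drow) == 1) {
        don[[length(don) + 1]] <- list(h = hrow, heavy = drow)
      }
    }
  }
  for (k in seq_len(nrow(acceptors))) {
    res <- structure[structure$code == acceptors$code[k] &
                       structure$atom == acceptors$atom[k], , drop = FALSE]
    if (nrow(res) > 0) {
      for (r in seq_len(nrow(res))) acc[[length(acc) + 1]] <- res[r, , drop = FALSE]
    }
  }
  out <- list()
  for (d in don) for (a in acc) {
    if (exclude_same_residue && d$h$chain == a$chain && d$h$resno == a$resno) next
    hd <- c(d$h$x, d$h$y, d$h$z); hv <- c(d$heavy$x, d$heavy$y, d$heavy$z)
    av <- c(a$x, a$y, a$z)
    dist <- dist_xyz(hd, av)
    if (dist > distance_cutoff) next
    v1 <- hv - hd; v2 <- av - hd
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
    if (ang < angle_cutoff) next
    out[[length(out) + 1]] <- data.frame(
      donor_chain = d$h$chain, donor_resno = d$h$resno, donor_code = d$h$code,
      h_atom = d$h$atom, acceptor_chain = a$chain, acceptor_resno = a$resno,
      acceptor_code = a$code, acceptor_atom = a$atom,
      distance = dist, angle = ang, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_code = character(), h_atom = character(),
                      acceptor_chain = character(), acceptor_resno = integer(),
                      acceptor_code = character(), acceptor_atom = character(),
                      distance = numeric(), angle = numeric()))
  }
  do.call(rbind, out)
}

#' Salt-bridge detection between lysine ammonium and carboxylate groups
#'
#' [hydrogen_bonds()] restricted to ammonium hydrogens (HZ1/HZ2/HZ3 on K) as
#' donors and carboxylate oxygens (OD1/OD2 on D, OE1/OE2 on E) as acceptors,
#' with the standard 3.0 Angstrom / 135 degree criteria.
#'
#' @param structure An `atomistic_structure`.
#' @param distance_cutoff,angle_cutoff Geometric criteria.
#' @return List `bridges` (bond table), `n`, `mean_length`, `mean_angle`.
#' @export
salt_bridges <- function(structure, distance_cutoff = 3.0, angle_cutoff = 135) {
  donors <- data.frame(code = "K", heavy = "NZ", h = c("HZ1", "HZ2", "HZ3"),
                       stringsAsFactors = FALSE)
  acceptors <- data.frame(code = c("D", "D", "E", "E"),
                          atom = c("OD1", "OD2", "OE1", "OE2"),
                          stringsAsFactors = FALSE)
  br <- hydrogen_bonds(structure, distance_cutoff, angle_cutoff,
                       donors, acceptors)
  list(bridges = br, n = nrow(br),
       mean_length = if (nrow(br) > 0) mean(br$distance) else NA_real_,
       mean_angle = if (nrow(br) > 0) mean(br$angle) else NA_real_)
}

#' Residue-pair contact map at a distance cutoff
#'
#' Counts atom pairs within `cutoff` Angstrom, aggregated by residue-code
#' pair.  Pairs of atoms within one residue are excluded by default (they
#' carry no interaction meaning); set `exclude_intra = FALSE` to count every
#' pair.
#'
#' @param structure An `atomistic_structure` (or any data frame with the same
#'   columns; the bead tables from [sheet_model_beads()] work with
#'   `atom = kind`).
#' @param cutoff Contact distance (Angstrom, default 7).
#' @param exclude_intra Exclude intra-residue pairs (default TRUE).
#' @return A symmetric named count matrix with attribute `cutoff`, classed
#'   `contact_map`.
#' @export
contact_map <- function(structure, cutoff = 7, exclude_intra = TRUE) {
  codes <- sort(unique(structure$code))
  m <- matrix(0L, length(codes), length(codes), dimnames = list(codes, codes))
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  reskey <- paste(structure$chain, structure$resno)
  n <- nrow(structure)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    hit <- js[d[i, js] <= cutoff]
    if (exclude_intra) hit <- hit[reskey[hit] != reskey[i]]
    for (j in hit) {
      a <- structure$code[i]; b <- structure$code[j]
      m[a, b] <- m[a, b] + 1L
      if (a != b) m[b, a] <- m[b, a] + 1L
    }
  }
  attr(m, "cutoff") <- cutoff
  class(m) <- c("contact_map", class(m))
  m
}

#' Count contacts between two atom selections
#'
#' @param structure An `atomistic_structure`.
#' @param sel_a,sel_b Disjoint row-index vectors (or logical masks).
#' @param cutoff Contact distance (Angstrom, default 7).
#' @return Number of atom pairs (one from each selection) within cutoff.
#' @export
group_contacts <- function(structure, sel_a, sel_b, cutoff = 7) {
  if (is.logical(sel_a)) sel_a <- which(sel_a)
  if (is.logical(sel_b)) sel_b <- which(sel_b)
  if (length(sel_a) == 0 || length(sel_b) == 0) stop("empty selection")
  if (length(intersect(sel_a, sel_b)) > 0) stop("selections must be disjoint")
  xa <- as.matrix(structure[sel_a, c("x", "y", "z")])
  xb <- as.matrix(structure[sel_b, c("x", "y", "z")])
  cnt <- 0L
  for (i in seq_len(nrow(xa))) {
    cnt <- cnt + sum(rowSums(sweep(xb, 2, xa[i, ], "-")^2) <= cutoff^2)
  }
  cnt
}

#' Minimal RMSD after optimal superposition (Kabsch)
#'
#' Translates both sets to their centroids and rotates `coords_b` onto
#' `coords_a` with the optimal proper rotation (SVD with determinant
#' correction), then returns the root-mean-square deviation.
#'
#' @param coords_a,coords_b Corresponded coordinate matrices (>= 3 rows,
#'   equal length).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate sets differ in length")
  if (nrow(coords_a) < 3) stop("need at least 3 points")
  a <- sweep(coords_a, 2, colMeans(coords_a), "-")
  b <- sweep(coords_b, 2, colMeans(coords_b), "-")
  sv <- svd(crossprod(b, a))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  br <- b %*% t(rot)
  sqrt(mean(rowSums((a - br)^2)))
}

ss_classes <- c("helix_310", "helix_alpha", "helix_pi", "bend", "turn",
                "coil", "strand")

#' Aggregate per-frame secondary-structure assignments
#'
#' Computes, for each residue, the mean occupancy of each secondary-structure
#' class over frames, and class totals (sums over residues).  The three helix
#' classes (3-10, alpha, pi) are additionally combined into a single `helix`
#' total.
#'
#' @param assignments Matrix (frames x residues) of class labels from
#'   `helix_310, helix_alpha, helix_pi, bend, turn, coil, strand`.
#' @return A `secondary_content` object: `per_residue` (residues x classes
#'   occupancy matrix) and `totals` (named vector including `helix`).
#' @export
aggregate_secondary <- function(assignments) {
  assignments <- as.matrix(assignments)
  bad <- setdiff(unique(as.vector(assignments)), ss_classes)
  if (length(bad) > 0) {
    stop("unknown secondary-structure class: ", paste(bad, collapse = ", "))
  }
  nres <- ncol(assignments)
  occ <- matrix(0, nres, length(ss_classes),
                dimnames = list(seq_len(nres), ss_classes))
  for (cl in ss_classes) occ[, cl] <- colMeans(assignments == cl)
  structure(list(per_residue = occ, totals = class_totals_matrix(occ)),
            class = "secondary_content")
}

class_totals_matrix <- function(occ) {
  tot <- colSums(occ)
  c(tot, helix = sum(tot[c("helix_310", "helix_alpha", "helix_pi")]))
}

#' Class totals of a secondary-content table
#'
#' Sums per-residue mean occupancies over residues; the helix entry is the
#' sum of the 3-10, alpha and pi helix classes.  Also accepts a plain
#' per-residue occupancy table (residues x classes) whose columns may
#' already be combined (e.g. a single `helix` column).
#'
#' @param x A `secondary_content` object, or a residues-x-classes matrix /
#'   data frame of occupancies.
#' @return Named vector of class totals.
#' @export
class_totals <- function(x) {
  if (inherits(x, "secondary_content")) return(x$totals)
  m <- as.matrix(x)
  colSums(m)
}
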