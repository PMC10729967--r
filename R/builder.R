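#' Ideal extended beta-strand coordinates
#'
#' Places a peptide in the extended beta template: CA beads along the strand
#' axis (y) with 3.5 Angstrom rise per residue, NH/CO beads zig-zagging in the
#' backbone (x-y) plane, and sidechain beads pleated on alternating sides of
#' the strand axis along z.  The strand is centred on the origin.
#'
#' @param seq A `catch_seq`.
#' @param representation `"four_bead"` (NH/CA/CO/R beads) or
#'   `"backbone_atomistic"` (records named N/CA/C at the backbone bead
#'   positions, for plane- and axis-based analyses of backbone geometry).
#' @param orientation `"+"` (N-to-C along +y) or `"-"` (along -y).
#' @param pleat `+1` or `-1`: sign of the sidechain offset of residue 1.
#' @param rise Rise per residue (Angstrom, default 3.5).
#' @return List with `coords` (matrix n_beads x 3), `beads` (metadata data
#'   frame), `topology`, `orientation`.
#' @export
ideal_strand <- function(seq, representation = c("four_bead", "backbone_atomistic"),
                         orientation = "+", pleat = 1, rise = 3.5) {
  representation <- match.arg(representation)
  stopifnot(orientation %in% c("+", "-"), pleat %in% c(-1, 1))
  topo <- build_topology(seq)
  geo <- template_geometry(rise)
  reg <- residue_registry()
  n <- length(seq$residues)
  y0 <- rise * (n - 1) / 2

  coords <- matrix(0, topo$n_beads, 3)
  for (i in seq_len(n)) {
    id <- topo$residue_index[[i]]
    s <- (-1)^(i - 1)
    yc <- rise * (i - 1) - y0
    coords[id["NH"], ] <- c(geo$p * s, yc - geo$d1, 0)
    coords[id["CA"], ] <- c(0, yc, 0)
    coords[id["CO"], ] <- c(geo$p * s, yc + geo$d2, 0)
    if ("R" %in% names(id)) {
      lr <- reg[seq$residues[i], "ca_r_length"]
      coords[id["R"], ] <- c(0, yc, s * pleat * lr)
    }
  }
  if (orientation == "-") coords[, 2] <- -coords[, 2]

  beads <- topo$beads
  if (representation == "backbone_atomistic") {
    keep <- beads$kind != "R"
    beads <- beads[keep, , drop = FALSE]
    beads$kind <- c(NH = "N", CA = "CA", CO = "C")[beads$kind]
    coords <- coords[keep, , drop = FALSE]
    rownames(beads) <- NULL
  }
  list(coords = coords, beads = beads, topology = topo, orientation = orientation)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Construct an in-register antiparallel charge-alternating beta-sheet
#'
#' Strands alternate between the cationic and the anionic peptide and between
#' `+` and `-` orientation (antiparallel).  Strand k is displaced by
#' `(k-1) * strand_spacing` along the sheet long axis (x) and rotated by
#' `(k-1) * twist_per_strand` degrees about that axis, producing a uniformly
#' twisted ribbon; negative twist is left-handed.  For the palindromic
#' CATCH class pattern (CQCFCFCFCQC) the antiparallel flip aligns residue
#' classes laterally across strands (class-level registration).
#'
#' @param seq_plus,seq_minus `catch_seq` objects for the cationic and anionic
#'   peptide.
#' @param n_strands Number of strands (>= 2, default 12).
#' @param strand_spacing Inter-strand spacing (Angstrom, default 5).
#' @param twist_per_strand Twist increment per strand (degrees, default 0).
#' @param pleat Pleat sign of residue 1 of strand 1 (controls which face the
#'   phenylalanine sidechains point to; default -1 puts them on +z).
#' @param z Sheet backbone-plane height (Angstrom).
#' @param sheet_id Integer tag recorded on each strand.
#' @return An object of class `sheet_model`; see [build_bilayer()].
#' @export
build_sheet <- function(seq_plus, seq_minus, n_strands = 12, strand_spacing = 5,
                        twist_per_strand = 0, pleat = -1, z = 0, sheet_id = 1L) {
  if (n_strands < 2) stop("n_strands must be >= 2")
  if (strand_spacing <= 0) stop("strand_spacing must be positive")
  strands <- vector("list", n_strands)
  for (k in seq_len(n_strands)) {
    sq <- if (k %% 2 == 1) seq_plus else seq_minus
    ori <- if (k %% 2 == 1) "+" else "-"
    st <- ideal_strand(sq, orientation = ori, pleat = pleat)
    co <- st$coords %*% t(rot_x((k - 1) * twist_per_strand))
    co[, 1] <- co[, 1] + (k - 1) * strand_spacing
    co[, 3] <- co[, 3] + z
    strands[[k]] <- list(seq = sq, topology = st$topology, coords = co,
                         orientation = ori, sheet = sheet_id,
                         net_charge = sq$net_charge, label = sq$label)
  }
  model <- structure(
    list(strands = strands, sheets = list(seq_len(n_strands)),
         params = list(strand_spacing = strand_spacing, sheet_gap = NA_real_,
                       twist_per_strand = twist_per_strand, mode = "sheet")),
    class = "sheet_model"
  )
  attr(model, "ground_truth") <- list(true_twist = twist_per_strand,
                                      true_spacing = strand_spacing,
                                      true_sheet_separations = numeric(0))
  model
}

#' @export
print.sheet_model <- function(x, ...) {
  cat(sprintf("<sheet_model> %d sheet(s), %d strands, mode '%s'\n",
              length(x$sheets), length(x$strands), x$params$mode))
  invisible(x)
}

merge_sheet_models <- function(models, mode, params, ground_truth) {
  strands <- list(); sheets <- list(); off <- 0
  for (m in models) {
    for (sh in m$sheets) sheets[[length(sheets) + 1]] <- sh + off
    strands <- c(strands, m$strands)
    off <- off + length(m$strands)
  }
  # re-tag sheet ids sequentially
  for (s in seq_along(sheets)) {
    for (k in sheets[[s]]) strands[[k]]$sheet <- s
  }
  params$mode <- mode
  model <- structure(list(strands = strands, sheets = sheets, params = params),
                     class = "sheet_model")
  attr(model, "ground_truth") <- ground_truth
  model
}

#' Construct an ideal beta-sheet bilayer
#'
#' Two sheets stacked along z with the phenylalanine sidechains of both
#' pointing into the gap (the hydrophobic core) and the charged sidechains
#' facing outward; the backbone planes are `sheet_gap` apart.
#'
#' @inheritParams build_sheet
#' @param sheet_gap Backbone-plane separation of the two sheets
#'   (Angstrom, default 13).
#' @return A `sheet_model` with two sheets and a `ground_truth` attribute
#'   recording the constructed twist, spacing and sheet separation.
#' @export
build_bilayer <- function(seq_plus, seq_minus, n_strands = 12, strand_spacing = 5,
                          twist_per_strand = 0, sheet_gap = 13, z = 0) {
  if (sheet_gap <= 0) stop("sheet_gap must be positive")
  s1 <- build_sheet(seq_plus, seq_minus, n_strands, strand_spacing,
                    twist_per_strand, pleat = -1, z = z, sheet_id = 1L)
  s2 <- build_sheet(seq_plus, seq_minus, n_strands, strand_spacing,
                    twist_per_strand, pleat = 1, z = z + sheet_gap, sheet_id = 2L)
  merge_sheet_models(
    list(s1, s2), "bilayer",
    list(strand_spacing = strand_spacing, sheet_gap = sheet_gap,
         twist_per_strand = twist_per_strand),
    list(true_twist = twist_per_strand, true_spacing = strand_spacing,
         true_sheet_separations = c("1-2" = sheet_gap))
  )
}

#' Mean inward sidechain reach of a sheet's charged residues
#'
#' The bilayer-stacking constructor measures tip-to-tip gaps from the mean
#' extended reach of the charged sidechains on a sheet face (the cationic and
#' anionic strands alternate, so the face tip plane is their average).
#'
#' @param seq_plus,seq_minus `catch_seq` objects.
#' @return Mean reach in Angstrom.
#' @export
charged_face_reach <- function(seq_plus, seq_minus) {
  reg <- residue_registry()
  r_of <- function(sq) {
    ch <- sq$residues[sq$classes %in% c("cationic", "anionic")]
    mean(reg[ch, "reach"])
  }
  (r_of(seq_plus) + r_of(seq_minus)) / 2
}

#' Construct two bilayers, stacked or separated
#'
#' Four sheets along z.  The charged sidechains of sheets 2 and 3 face each
#' other across the inter-bilayer gap.  In `"stacked"` mode the inward
#' sidechain tip planes of sheets 2 and 3 are 3 Angstrom apart; in
#' `"separated"` mode they are 13 Angstrom apart (10 Angstrom more).  Tip
#' planes are the backbone plane offset by the mean extended reach of the
#' face's charged sidechains, so for the K/E pair the stacked backbone-plane
#' distance between sheets 2 and 3 is 14.8 Angstrom and for K/D 12.7.
#'
#' @inheritParams build_bilayer
#' @param mode `"stacked"` or `"separated"`.
#' @param tip_gap Tip-plane gap override (Angstrom); defaults to 3 (stacked)
#'   or 13 (separated).
#' @return A `sheet_model` with four sheets; `ground_truth` records all three
#'   adjacent sheet separations.
#' @export
build_two_bilayers <- function(seq_plus, seq_minus, mode = c("stacked", "separated"),
                               n_strands = 12, strand_spacing = 5,
                               twist_per_strand = 0, sheet_gap = 13,
                               tip_gap = NULL) {
  mode <- match.arg(mode)
  if (is.null(tip_gap)) tip_gap <- if (mode == "stacked") 3 else 13
  reach <- charged_face_reach(seq_plus, seq_minus)
  gap23 <- 2 * reach + tip_gap
  b1 <- build_bilayer(seq_plus, seq_minus, n_strands, strand_spacing,
                      twist_per_strand, sheet_gap, z = 0)
  b2 <- build_bilayer(seq_plus, seq_minus, n_strands, strand_spacing,
                      twist_per_strand, sheet_gap, z = sheet_gap + gap23)
  merge_sheet_models(
    list(b1, b2), mode,
    list(strand_spacing = strand_spacing, sheet_gap = sheet_gap,
         twist_per_strand = twist_per_strand, tip_gap = tip_gap,
         layer_gaps = c(sheet_gap, gap23, sheet_gap)),
    list(true_twist = twist_per_strand, true_spacing = strand_spacing,
         true_sheet_separations = c("1-2" = sheet_gap, "2-3" = gap23,
                                    "3-4" = sheet_gap))
  )
}

#' Extract per-strand CA coordinates from a sheet model
#' @param model A `sheet_model`.
#' @return List of matrices (one per strand, rows in N-to-C order).
#' @export
strand_ca_coords <- function(model) {
  lapply(model$strands, function(st) {
    ids <- vapply(st$topology$residue_index, function(x) x[["CA"]], numeric(1))
    st$coords[ids, , drop = FALSE]
  })
}

#' Backbone bead coordinates of one sheet
#' @param model A `sheet_model`.
#' @param sheet Sheet number.
#' @export
sheet_backbone_coords <- function(model, sheet) {
  ks <- model$sheets[[sheet]]
  do.call(rbind, lapply(model$strands[ks], function(st) {
    st$coords[st$topology$beads$kind != "R", , drop = FALSE]
  }))
}

#' All beads of a sheet model as a flat table
#' @param model A `sheet_model`.
#' @return Data frame: `peptide`, `sheet`, `residue`, `kind`, `code`, `x`,
#'   `y`, `z`.
#' @export
sheet_model_beads <- function(model) {
  out <- lapply(seq_along(model$strands), function(k) {
    st <- model$strands[[k]]
    b <- st$topology$beads
    data.frame(peptide = k, sheet = st$sheet, residue = b$residue,
               kind = b$kind, code = b$code,
               x = st$coords[, 1], y = st$coords[, 2], z = st$coords[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
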