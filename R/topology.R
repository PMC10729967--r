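#' Backbone template geometry for the four-bead model
#'
#' The model's reference conformation is an extended beta-strand: CA beads on
#' the strand axis with a rise of `rise` Angstrom per residue, NH and CO beads
#' offset laterally by `p` on alternating sides (the backbone zig-zag), and
#' sidechain beads pleated perpendicular to the backbone plane.  The lateral
#' offset is solved so that the three backbone bond lengths take their
#' standard values (NH-CA 1.46, CA-CO 1.51, CO-NH' 1.33 Angstrom) exactly.
#' All pseudobond nominal lengths are derived from this template, so ideal
#' builds satisfy every DMD bond constraint by construction.
#'
#' @param rise Rise per residue along the strand axis (Angstrom).
#' @return List with `rise`, `p` (lateral NH/CO offset), `d1` (NH back-shift),
#'   `d2` (CO forward-shift) and derived pseudobond lengths.
#' @export
template_geometry <- function(rise = 3.5) {
  b_nh_ca <- 1.46; b_ca_co <- 1.51; b_co_nh <- 1.33
  f <- function(q) {
    4 * q + (rise - sqrt(b_nh_ca^2 - q) - sqrt(b_ca_co^2 - q))^2 - b_co_nh^2
  }
  q <- stats::uniroot(f, c(1e-8, b_nh_ca^2 - 1e-8), tol = 1e-14)$root
  p <- sqrt(q)
  d1 <- sqrt(b_nh_ca^2 - q)
  d2 <- sqrt(b_ca_co^2 - q)
  list(
    rise = rise, p = p, d1 = d1, d2 = d2,
    nh_ca = b_nh_ca, ca_co = b_ca_co, co_nh = b_co_nh,
    nh_co = d1 + d2,                                  # intra-residue pseudobond
    ca_ca = rise,                                     # CA(i)-CA(i+1)
    ca_nh_next = sqrt(q + (rise - d1)^2),             # CA(i)-NH(i+1)
    co_ca_next = sqrt(q + (rise - d2)^2)              # CO(i)-CA(i+1)
  )
}

#' Build the four-bead topology of a peptide
#'
#' Each residue contributes an NH, CA and CO backbone bead plus one sidechain
#' bead R (glycine contributes no R bead).  Backbone beads carry united-atom
#' masses (NH 15.015, CA 13.019, CO 28.010 amu); the R bead carries the
#' residue's sidechain mass.  Covalent bonds (NH-CA, CA-CO, CO-NH of the next
#' residue, CA-R) and geometry-maintaining pseudobonds (NH-CO within a
#' residue, CA-CA', CA-NH', CO-CA', R-NH, R-CO) are hard-wall constraints kept
#' within `(1 - delta, 1 + delta)` times their nominal length.  The pseudobond
#' set leaves the phi/psi torsions free while locking bond angles and the
#' trans peptide plane.
#'
#' @param seq A `catch_seq` from [sequence_from_string()].
#' @param delta Fractional bond tolerance (default 0.02375).
#' @return An object of class `catch_topology` with `beads` (data frame:
#'   `residue`, `kind`, `mass`, `sigma`, `code`) and `bonds` (data frame:
#'   `i`, `j`, `length`, `delta`, `kind`).
#' @export
build_topology <- function(seq, delta = 0.02375) {
  stopifnot(inherits(seq, "catch_seq"))
  if (delta <= 0 || delta >= 0.1) stop("delta must lie in (0, 0.1)")
  reg <- residue_registry()
  geo <- template_geometry()
  m_bb <- c(NH = 15.015, CA = 13.019, CO = 28.010)
  sig_bb <- c(NH = 3.3, CA = 3.7, CO = 3.6)

  n <- length(seq$residues)
  beads <- list(); idx <- list()
  k <- 0
  for (i in seq_len(n)) {
    code <- seq$residues[i]
    has_r <- reg[code, "has_sidechain"]
    kinds <- c("NH", "CA", "CO", if (has_r) "R")
    ids <- k + seq_along(kinds); k <- k + length(kinds)
    idx[[i]] <- stats::setNames(ids, kinds)
    beads[[i]] <- data.frame(
      residue = i, kind = kinds,
      mass = c(m_bb, if (has_r) reg[code, "sidechain_mass"]),
      sigma = c(sig_bb, if (has_r) reg[code, "sigma"]),
      code = code, stringsAsFactors = FALSE
    )
  }
  beads <- do.call(rbind, beads)
  rownames(beads) <- NULL

  bonds <- list()
  add <- function(a, b, len, kind) {
    bonds[[length(bonds) + 1]] <<- data.frame(i = a, j = b, length = len,
                                              delta = delta, kind = kind,
                                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    id <- idx[[i]]
    code <- seq$residues[i]
    add(id["NH"], id["CA"], geo$nh_ca, "bond")
    add(id["CA"], id["CO"], geo$ca_co, "bond")
    add(id["NH"], id["CO"], geo$nh_co, "pseudo")
    if ("R" %in% names(id)) {
      lr <- reg[code, "ca_r_length"]
      add(id["CA"], id["R"], lr, "bond")
      add(id["R"], id["NH"], sqrt(lr^2 + geo$nh_ca^2), "pseudo")
      add(id["R"], id["CO"], sqrt(lr^2 + geo$ca_co^2), "pseudo")
    }
    if (i < n) {
      id2 <- idx[[i + 1]]
      add(id["CO"], id2["NH"], geo$co_nh, "bond")
      add(id["CA"], id2["CA"], geo$ca_ca, "pseudo")
      add(id["CA"], id2["NH"], geo$ca_nh_next, "pseudo")
      add(id["CO"], id2["CA"], geo$co_ca_next, "pseudo")
    }
  }
  bonds <- do.call(rbind, bonds)
  rownames(bonds) <- NULL

  structure(
    list(sequence = seq, beads = beads, bonds = bonds,
         residue_index = idx, n_beads = nrow(beads), delta = delta),
    class = "catch_topology"
  )
}

#' @export
print.catch_topology <- function(x, ...) {
  cat(sprintf("<catch_topology> %s: %d beads, %d bonds (%d covalent, %d pseudo)\n",
              x$sequence$label, x$n_beads, nrow(x$bonds),
              sum(x$bonds$kind == "bond"), sum(x$bonds$kind == "pseudo")))
  invisible(x)
}

#' Total mass of a topology (amu)
#' @param topology A `catch_topology`.
#' @export
topology_mass <- function(topology) sum(topology$beads$mass)

#' Is the bond graph of a topology connected?
#' @param topology A `catch_topology`.
#' @return TRUE if every bead is reachable from bead 1 along bonds/pseudobonds.
#' @export
topology_connected <- function(topology) {
  g <- igraph::graph_from_edgelist(as.matrix(topology$bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, topology$n_beads - igraph::vcount(g)))
  igraph::components(g)$no == 1
}
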