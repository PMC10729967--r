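#' Assemble a multi-peptide DMD system state
#'
#' Concatenates per-peptide topologies and coordinates into the flat arrays
#' the event-driven engine consumes: bead metadata, global bond walls,
#' positions, velocities, the periodic box and the hydrogen-bond registry
#' (a partial matching NH -> CO, at most one partner each).
#'
#' @param peptides List of `list(topology = <catch_topology>,
#'   coords = <n_beads x 3 matrix>)`.
#' @param box Cubic box side length (Angstrom), or `NULL` for unbounded
#'   analysis-only systems.
#' @param velocities Optional N x 3 matrix (reduced units); zero if missing.
#' @param time Initial reduced time.
#' @return An object of class `dmd_state`.
#' @export
make_system <- function(peptides, box = NULL, velocities = NULL, time = 0) {
  beads <- list(); bonds <- list(); pos <- list()
  off <- 0
  for (p in seq_along(peptides)) {
    tp <- peptides[[p]]$topology
    co <- peptides[[p]]$coords
    stopifnot(nrow(co) == tp$n_beads)
    b <- tp$beads
    b$peptide <- p
    beads[[p]] <- b
    bd <- tp$bonds
    bd$i <- bd$i + off; bd$j <- bd$j + off
    bonds[[p]] <- bd
    pos[[p]] <- co
    off <- off + tp$n_beads
  }
  beads <- do.call(rbind, beads); rownames(beads) <- NULL
  bonds <- do.call(rbind, bonds); rownames(bonds) <- NULL
  pos <- do.call(rbind, pos)
  n <- nrow(pos)
  if (!is.null(box)) pos <- pos - floor(pos / box) * box
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  structure(
    list(beads = beads, bonds = bonds, pos = pos, vel = velocities,
         box = box, hb_partner = integer(n), time = time,
         n_peptides = length(peptides)),
    class = "dmd_state"
  )
}

#' @export
print.dmd_state <- function(x, ...) {
  cat(sprintf("<dmd_state> %d peptides, %d beads, box %s, t = %.3f, %d H-bonds\n",
              x$n_peptides, nrow(x$pos),
              if (is.null(x$box)) "none" else sprintf("%.1f A", x$box),
              x$time, sum(x$hb_partner > 0) / 2))
  invisible(x)
}

#' Convert a built sheet model into a DMD system state
#' @param model A `sheet_model`.
#' @param box Optional cubic box length; defaults to twice the structure
#'   extent so periodic images do not interact.
#' @export
sheet_model_system <- function(model, box = NULL) {
  peps <- lapply(model$strands, function(st) {
    list(topology = st$topology, coords = st$coords)
  })
  if (is.null(box)) {
    all_xyz <- do.call(rbind, lapply(model$strands, `[[`, "coords"))
    box <- 2 * max(apply(all_xyz, 2, function(v) diff(range(v)))) + 30
    shift <- box / 2 - colMeans(all_xyz)
    peps <- lapply(peps, function(p) { p$coords <- sweep(p$coords, 2, shift, "+"); p })
  }
  make_system(peps, box = box)
}

#' Draw Maxwell-Boltzmann velocities at a reduced temperature
#'
#' Each Cartesian component of bead i is Normal(0, sqrt(T*/m_i)); the centre
#' of mass drift is removed.
#'
#' @param masses Bead masses (amu).
#' @param t_star Reduced temperature.
#' @return N x 3 velocity matrix (reduced units).
#' @export
maxwell_velocities <- function(masses, t_star) {
  n <- length(masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(t_star / masses)
  drift <- colSums(v * masses) / sum(masses)
  sweep(v, 2, drift, "-")
}

pair_min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

#' Nonbonded interaction classification used throughout the package
#'
#' Beads in the same or adjacent residues of one peptide interact only
#' through their bond/pseudobond walls.  All other pairs carry a hard core
#' (arithmetic-mean diameter); sidechain pairs separated by at least three
#' residues (or on different peptides) may additionally carry a square well
#' from the interaction table, and NH-CO pairs on different peptides (or at
#' least four residues apart) are hydrogen-bond candidates.
#'
#' @param state A `dmd_state`.
#' @param table An `interaction_table`.
#' @param i,j Bead indices.
#' @return List `excluded`, `sigma`, `lambda`, `epsilon`, `hb_candidate`.
#' @export
classify_pair <- function(state, table, i, j) {
  b <- state$beads
  same_pep <- b$peptide[i] == b$peptide[j]
  dres <- abs(b$residue[i] - b$residue[j])
  if (same_pep && dres <= 1) {
    return(list(excluded = TRUE, sigma = NA_real_, lambda = NA_real_,
                epsilon = 0, hb_candidate = FALSE))
  }
  sig_of <- function(k) {
    if (b$kind[k] == "R") table$sigma_sidechain[[b$code[k]]]
    else table$sigma_backbone[[b$kind[k]]]
  }
  sigma <- (sig_of(i) + sig_of(j)) / 2
  lambda <- NA_real_; epsilon <- 0
  if (b$kind[i] == "R" && b$kind[j] == "R" && (!same_pep || dres >= 3)) {
    w <- pair_well(table, b$code[i], b$code[j])
    lambda <- w$lambda; epsilon <- w$epsilon
  }
  hb <- (((b$kind[i] == "NH" && b$kind[j] == "CO") ||
          (b$kind[i] == "CO" && b$kind[j] == "NH")) &&
         (!same_pep || dres >= 4))
  list(excluded = FALSE, sigma = sigma, lambda = lambda, epsilon = epsilon,
       hb_candidate = hb)
}

#' Check the state invariants of a DMD system
#'
#' No non-bonded pair closer than its hard core, every bonded pair within its
#' walls, hydrogen-bond registry a partial matching within range.
#'
#' @param state A `dmd_state`.
#' @param table An `interaction_table`.
#' @param tol Slack for floating-point placement.
#' @return TRUE invisibly, or stops with a diagnostic.
#' @export
validate_state <- function(state, table, tol = 1e-9) {
  n <- nrow(state$pos)
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(state$bonds$i, state$bonds$j)] <- TRUE
  bonded[cbind(state$bonds$j, state$bonds$i)] <- TRUE
  for (i in seq_len(n - 1)) {
    d <- pair_min_image(state$pos[(i + 1):n, , drop = FALSE][, ] -
                          matrix(state$pos[i, ], n - i, 3, byrow = TRUE), state$box)
    r <- sqrt(rowSums(d^2))
    for (kk in seq_along(r)) {
      j <- i + kk
      if (bonded[i, j]) next
      cl <- classify_pair(state, table, i, j)
      if (cl$excluded) next
      if (r[kk] < cl$sigma * (1 - tol) - tol) {
        stop(sprintf("core overlap: beads %d-%d at %.4f < sigma %.4f", i, j, r[kk], cl$sigma))
      }
    }
  }
  db <- pair_min_image(state$pos[state$bonds$j, , drop = FALSE] -
                         state$pos[state$bonds$i, , drop = FALSE], state$box)
  rb <- sqrt(rowSums(db^2))
  lo <- state$bonds$length * (1 - state$bonds$delta)
  hi <- state$bonds$length * (1 + state$bonds$delta)
  bad <- which(rb < lo * (1 - tol) - tol | rb > hi * (1 + tol) + tol)
  if (length(bad) > 0) {
    stop(sprintf("bond wall violation: pair %d-%d at %.4f not in [%.4f, %.4f]",
                 state$bonds$i[bad[1]], state$bonds$j[bad[1]], rb[bad[1]],
                 lo[bad[1]], hi[bad[1]]))
  }
  hb <- state$hb_partner
  reg <- which(hb > 0)
  if (any(hb[hb[reg]] != reg)) stop("hydrogen-bond registry is not a matching")
  invisible(TRUE)
}
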