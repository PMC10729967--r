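rodrigues <- function(pts, origin, axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  p <- sweep(pts, 2, origin, "-")
  cosT <- cos(theta); sinT <- sin(theta)
  dotp <- p %*% u
  crossp <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
                  u[3] * p[, 1] - u[1] * p[, 3],
                  u[1] * p[, 2] - u[2] * p[, 1])
  out <- p * cosT + crossp * sinT + (dotp %*% t(u)) * (1 - cosT)
  sweep(out, 2, origin, "+")
}

random_rotation_matrix <- function() {
  # uniform over SO(3) via quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
         3, 3)
}

intra_overlap_free <- function(coords, topo, table) {
  b <- topo$beads
  n <- nrow(coords)
  sig_of <- function(k) {
    if (b$kind[k] == "R") table$sigma_sidechain[[b$code[k]]]
    else table$sigma_backbone[[b$kind[k]]]
  }
  sig <- vapply(seq_len(n), sig_of, numeric(1))
  for (i in seq_len(n - 1)) {
    js <- which(abs(b$residue - b$residue[i]) >= 2)
    js <- js[js > i]
    if (length(js) == 0) next
    d2 <- rowSums(sweep(coords[js, , drop = FALSE], 2, coords[i, ], "-")^2)
    if (any(d2 < ((sig[i] + sig[js]) / 2)^2)) return(FALSE)
  }
  TRUE
}

self_image_free <- function(coords, topo, table, box) {
  b <- topo$beads
  sig_of <- function(k) {
    if (b$kind[k] == "R") table$sigma_sidechain[[b$code[k]]]
    else table$sigma_backbone[[b$kind[k]]]
  }
  sig <- vapply(seq_len(nrow(coords)), sig_of, numeric(1))
  for (i in seq_len(nrow(coords) - 1)) {
    js <- which(abs(b$residue - b$residue[i]) >= 2)
    js <- js[js > i]
    if (length(js) == 0) next
    d <- sweep(coords[js, , drop = FALSE], 2, coords[i, ], "-")
    d <- d - box * round(d / box)
    if (any(rowSums(d^2) < ((sig[i] + sig[js]) / 2)^2)) return(FALSE)
  }
  TRUE
}

#' Generate a random-coil conformation of one peptide
#'
#' Starts from the extended template and applies random phi/psi pivot
#' rotations (which preserve every bond and pseudobond wall of the four-bead
#' topology exactly), rejecting moves that create intra-peptide hard-core
#' overlaps — a self-avoiding walk over the model's torsional degrees of
#' freedom.
#'
#' @param seq A `catch_seq`.
#' @param table An `interaction_table` (for overlap rejection).
#' @param n_moves Number of accepted pivot moves attempted (default 2 sweeps).
#' @param max_angle Maximum pivot angle magnitude (radians).
#' @return List `topology`, `coords`.
#' @export
random_coil_conformation <- function(seq, table = default_interaction_table(),
                                     n_moves = NULL, max_angle = pi / 2) {
  st <- ideal_strand(seq)
  topo <- st$topology
  coords <- st$coords
  n <- length(seq$residues)
  if (is.null(n_moves)) n_moves <- 2 * n
  accepted <- 0; attempts <- 0
  while (accepted < n_moves && attempts < 50 * n_moves) {
    attempts <- attempts + 1
    i <- sample.int(n, 1)
    id <- topo$residue_index[[i]]
    phi <- stats::runif(1) < 0.5
    theta <- stats::runif(1, -max_angle, max_angle)
    if (phi) {
      # rotate CO_i, R_i and residues > i about the NH_i -> CA_i axis
      axis_a <- coords[id[["NH"]], ]; axis_b <- coords[id[["CA"]], ]
      movers <- c(id[["CO"]], if ("R" %in% names(id)) id[["R"]],
                  unlist(topo$residue_index[seq_len(n) > i]))
    } else {
      # rotate residues > i about the CA_i -> CO_i axis
      if (i == n) next
      axis_a <- coords[id[["CA"]], ]; axis_b <- coords[id[["CO"]], ]
      movers <- unlist(topo$residue_index[seq_len(n) > i])
    }
    trial <- coords
    trial[movers, ] <- rodrigues(coords[movers, , drop = FALSE],
                                 axis_a, axis_b - axis_a, theta)
    if (intra_overlap_free(trial, topo, table)) {
      coords <- trial
      accepted <- accepted + 1
    }
  }
  coords <- sweep(coords, 2, colMeans(coords), "-")
  list(topology = topo, coords = coords)
}

#' Random-coil peptide dispersion in a periodic cubic box
#'
#' Places `n_plus` cationic and `n_minus` anionic peptides in random-coil
#' conformations at random positions and orientations in a cubic periodic
#' box, with no inter-peptide bead pair closer than `min_separation`
#' (minimum-image), and draws Maxwell-Boltzmann velocities at `t_star`.
#' Reproducible under a fixed seed.
#'
#' @param seq_plus,seq_minus `catch_seq` objects.
#' @param n_plus,n_minus Copy numbers.
#' @param box_length Cubic box side (Angstrom).
#' @param min_separation Minimum inter-peptide bead distance (Angstrom).
#' @param t_star Reduced temperature for the velocity draw.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param table Interaction table used for conformation self-avoidance.
#' @param max_tries Placement attempts per peptide before giving up.
#' @return A `dmd_state`.
#' @export
random_coil_box <- function(seq_plus, seq_minus, n_plus, n_minus, box_length,
                            min_separation = 5, t_star = 0.18, seed = NULL,
                            table = default_interaction_table(),
                            max_tries = 200) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  species <- c(rep(list(seq_plus), n_plus), rep(list(seq_minus), n_minus))
  placed <- list()
  occ <- NULL   # all placed bead coords
  for (p in seq_along(species)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      conf <- random_coil_conformation(species[[p]], table)
      co <- conf$coords %*% t(random_rotation_matrix())
      com <- stats::runif(3, 0, box_length)
      co <- sweep(co, 2, com, "+")
      co <- co - floor(co / box_length) * box_length
      # a sprawling coil can fold back onto itself through the periodic
      # boundary: reject conformations with minimum-image self-overlaps
      if (!self_image_free(co, conf$topology, table, box_length)) next
      if (!is.null(occ)) {
        clash <- FALSE
        for (k in seq_len(nrow(co))) {
          d <- sweep(occ, 2, co[k, ], "-")
          d <- d - box_length * round(d / box_length)
          if (min(rowSums(d^2)) < min_separation^2) { clash <- TRUE; break }
        }
        if (clash) next
      }
      placed[[p]] <- list(topology = conf$topology, coords = co)
      occ <- rbind(occ, co)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf("packing failed: placed %d of %d peptides at min separation %.1f A",
                   p - 1, length(species), min_separation))
    }
  }
  st <- make_system(placed, box = box_length)
  st$vel <- maxwell_velocities(st$beads$mass, t_star)
  st
}
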