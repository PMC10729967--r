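#' Atomistic salt-bridge micro-fixture
#'
#' One lysine ammonium group and one carboxylate group placed so that the
#' H...O distance and the N-H...O angle are exactly as requested.  The two
#' spectator ammonium hydrogens point away from the acceptor.  Used to
#' exercise the salt-bridge detector at known geometry.
#'
#' @param distance H...O distance (Angstrom, > 0).
#' @param angle N-H...O angle (degrees, in (0, 180]).
#' @param acceptor `"E"` (glutamate, OE1/OE2) or `"D"` (aspartate, OD1/OD2).
#' @return An `atomistic_structure` with a K residue (chain A) and the
#'   acceptor residue (chain B).
#' @export
salt_bridge_fixture <- function(distance, angle, acceptor = c("E", "D")) {
  acceptor <- match.arg(acceptor)
  if (distance <= 0) stop("distance must be positive")
  if (angle <= 0 || angle > 180) stop("angle must lie in (0, 180] degrees")
  nh <- 1.04                      # N-H bond length
  nz <- c(0, 0, 0)
  h1 <- c(nh, 0, 0)
  a <- pi - angle * pi / 180      # direction of O - H relative to +x
  o1 <- h1 + distance * c(cos(a), sin(a), 0)
  # spectator hydrogens: tetrahedral-ish, pointing away from the acceptor
  h2 <- nz + nh * c(-0.36, -0.60, 0.72)
  h3 <- nz + nh * c(-0.36, -0.60, -0.72)
  onames <- if (acceptor == "E") c("OE1", "OE2") else c("OD1", "OD2")
  cname <- if (acceptor == "E") "CD" else "CG"
  cd <- o1 + c(1.25, 0, 0)
  o2 <- cd + c(0.6, 1.1, 0)
  df <- data.frame(
    chain = c("A", "A", "A", "A", "B", "B", "B"),
    resno = c(1L, 1L, 1L, 1L, 1L, 1L, 1L),
    code = c("K", "K", "K", "K", acceptor, acceptor, acceptor),
    atom = c("NZ", "HZ1", "HZ2", "HZ3", onames[1], cname, onames[2]),
    elem = c("N", "H", "H", "H", "O", "C", "O"),
    x = c(nz[1], h1[1], h2[1], h3[1], o1[1], cd[1], o2[1]),
    y = c(nz[2], h1[2], h2[2], h3[2], o1[2], cd[2], o2[2]),
    z = c(nz[3], h1[3], h2[3], h3[3], o1[3], cd[3], o2[3]),
    stringsAsFactors = FALSE
  )
  atomistic_structure(df)
}

place_cluster <- function(members, class, seq_of, origin_x) {
  # returns list(per-peptide coords keyed by peptide index, hb pairs)
  k <- length(members)
  coords <- list()
  if (class == "barrel") {
    radius <- max(6, k * 5 / (2 * pi))
    for (s in seq_len(k)) {
      st <- ideal_strand(seq_of(members[s]))
      th <- 2 * pi * (s - 1) / k
      co <- st$coords
      co[, c(1, 3)] <- co[, c(1, 3)] %*%
        matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      co[, 1] <- co[, 1] + origin_x + radius * cos(th)
      co[, 3] <- co[, 3] + radius * sin(th)
      coords[[as.character(members[s])]] <- co
    }
  } else {
    for (s in seq_len(k)) {
      st <- ideal_strand(seq_of(members[s]),
                         orientation = if (s %% 2 == 1) "+" else "-")
      co <- st$coords
      co[, 1] <- co[, 1] + origin_x + (s - 1) * 5
      coords[[as.character(members[s])]] <- co
    }
  }
  hb <- NULL
  if (class %in% c("sheet", "barrel")) {
    pairs <- cbind(members[-k], members[-1])
    if (class == "barrel") pairs <- rbind(pairs, c(members[k], members[1]))
    hb <- pairs
  }
  list(coords = coords, hb_pairs = hb)
}

#' Scripted assembly trajectory with known cluster ground truth
#'
#' Builds a synthetic trajectory whose connectivity analysis must reproduce a
#' prescribed per-frame clustering: each frame lists clusters as member sets
#' with a geometry class (`"sheet"`: strands linked in an open hydrogen-bond
#' ladder; `"barrel"`: the ladder closed into a cycle; `"oligomer"`: peptides
#' in contact without a hydrogen-bond ladder); unlisted peptides are free.
#' Sheet/barrel clusters carry `hb_per_interface` registered hydrogen bonds
#' between consecutive strands; clusters are placed far apart so no spurious
#' links arise.  Used to exercise the cluster census, the beta-barrel
#' classifier and barrel-to-sheet transition detection against ground truth.
#'
#' @param n_peptides Number of peptides (odd indices cationic, even anionic).
#' @param frames List of frame scripts; each is a list of
#'   `list(members = <indices>, class = "sheet"|"barrel"|"oligomer")`.
#' @param seq_plus,seq_minus Sequences for odd/even peptide indices.
#' @param hb_per_interface Registered H-bonds per consecutive strand pair
#'   (default 5, the connection threshold).
#' @param times Frame times (default `seq_along(frames)`).
#' @return A `dmd_trajectory` with attribute `ground_truth` (per-frame member
#'   sets and classes as scripted).
#' @export
scripted_trajectory <- function(n_peptides, frames,
                                seq_plus = catch_sequence("6K"),
                                seq_minus = catch_sequence("6E"),
                                hb_per_interface = 5,
                                times = seq_along(frames)) {
  seq_of <- function(i) if (i %% 2 == 1) seq_plus else seq_minus
  peps <- lapply(seq_len(n_peptides), function(i) {
    st <- ideal_strand(seq_of(i))
    list(topology = st$topology, coords = st$coords)
  })
  base <- make_system(peps, box = NULL)
  bead_of <- function(pep, res, kind) {
    which(base$beads$peptide == pep & base$beads$residue == res &
            base$beads$kind == kind)
  }

  out_frames <- list()
  truth <- list()
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    members_all <- unlist(lapply(fr, `[[`, "members"))
    if (anyDuplicated(members_all)) {
      stop("inconsistent script: peptide ",
           members_all[duplicated(members_all)][1],
           " appears in two clusters in frame ", f)
    }
    if (any(members_all > n_peptides)) stop("script names unknown peptides")
    pos <- base$pos
    partner <- integer(nrow(pos))
    slot <- 0
    for (cl in fr) {
      slot <- slot + 1
      pl <- place_cluster(cl$members, cl$class, seq_of, origin_x = 200 * slot)
      for (m in names(pl$coords)) {
        pidx <- as.integer(m)
        rows <- which(base$beads$peptide == pidx)
        pos[rows, ] <- pl$coords[[m]]
      }
      if (!is.null(pl$hb_pairs)) {
        for (r in seq_len(nrow(pl$hb_pairs))) {
          a <- pl$hb_pairs[r, 1]; b <- pl$hb_pairs[r, 2]
          for (res in seq_len(hb_per_interface)) {
            nh <- bead_of(a, res, "NH"); co <- bead_of(b, res, "CO")
            partner[nh] <- co; partner[co] <- nh
          }
        }
      }
    }
    free <- setdiff(seq_len(n_peptides), members_all)
    for (fi in seq_along(free)) {
      rows <- which(base$beads$peptide == free[fi])
      pos[rows, 1] <- pos[rows, 1] + 200 * (slot + fi) + 5000
    }
    out_frames[[f]] <- list(pos = pos, time = times[f], hb_partner = partner)
    truth[[f]] <- list(
      clusters = lapply(fr, function(cl) {
        list(members = as.integer(sort(cl$members)),
             class = c(sheet = "beta_sheet", barrel = "beta_barrel",
                       oligomer = "oligomer")[[cl$class]])
      }),
      free = free
    )
  }
  traj <- structure(
    list(frames = out_frames, beads = base$beads, bonds = base$bonds,
         box = NULL, n_peptides = n_peptides),
    class = "dmd_trajectory"
  )
  attr(traj, "ground_truth") <- truth
  traj
}
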