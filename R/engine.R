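kind_code <- c(NH = 0L, CA = 1L, CO = 2L, R = 3L)

engine_arrays <- function(state, table) {
  b <- state$beads
  reg_codes <- residue_registry()$code
  sig <- ifelse(b$kind == "R",
                as.numeric(table$sigma_sidechain[b$code]),
                as.numeric(table$sigma_backbone[b$kind]))
  nc <- length(reg_codes)
  wl <- matrix(0, nc, nc); we <- matrix(0, nc, nc)
  if (nrow(table$wells) > 0) {
    ia <- match(table$wells$a, reg_codes); ib <- match(table$wells$b, reg_codes)
    for (k in seq_along(ia)) {
      wl[ia[k], ib[k]] <- wl[ib[k], ia[k]] <- table$wells$lambda[k]
      we[ia[k], ib[k]] <- we[ib[k], ia[k]] <- table$wells$epsilon[k]
    }
  }
  n <- nrow(b)
  key <- paste(b$peptide, b$residue, b$kind)
  find_bead <- function(pep, res, kind) {
    hit <- match(paste(pep, res, kind), key)
    ifelse(is.na(hit), 0L, hit)
  }
  nbr_ca <- ifelse(b$kind %in% c("NH", "CO"),
                   find_bead(b$peptide, b$residue, "CA"), 0L)
  nbr_prev_co <- ifelse(b$kind == "NH",
                        find_bead(b$peptide, b$residue - 1, "CO"), 0L)
  nbr_next_nh <- ifelse(b$kind == "CO",
                        find_bead(b$peptide, b$residue + 1, "NH"), 0L)
  list(
    sigma = sig,
    peptide = as.integer(b$peptide), residue = as.integer(b$residue),
    kind = unname(kind_code[b$kind]),
    rcode = match(b$code, reg_codes) - 1L,
    bonds = cbind(as.integer(state$bonds$i - 1), as.integer(state$bonds$j - 1)),
    bond_lo = state$bonds$length * (1 - state$bonds$delta),
    bond_hi = state$bonds$length * (1 + state$bonds$delta),
    well_lambda = wl, well_eps = we,
    nbr_ca = as.integer(nbr_ca - 1L), nbr_prev_co = as.integer(nbr_prev_co - 1L),
    nbr_next_nh = as.integer(nbr_next_nh - 1L),
    cell_range = max(table$hbond$range,
                     if (nrow(table$wells) > 0) max(table$wells$lambda) else 0,
                     max(sig),
                     max(state$bonds$length * (1 + state$bonds$delta))) + 1e-9
  )
}

#' Run event-driven DMD on a peptide system
#'
#' Propagates the system exactly between discrete events: hard-core
#' collisions, square-well capture/escape/bounce, bond and pseudobond wall
#' reflections, directional NH-CO hydrogen-bond association/dissociation
#' (one partner per bead, auxiliary neighbour-distance criteria evaluated at
#' association), Andersen-thermostat ghost collisions at `ghost_rate` per
#' bead per reduced time unit, and cell-list bookkeeping.  Deterministic
#' under a fixed seed.
#'
#' @param state A `dmd_state` with a positive cubic box.
#' @param table An `interaction_table`.
#' @param t_star Reduced temperature for the thermostat.
#' @param ghost_rate Ghost-collision rate per bead per reduced time
#'   (0 disables the thermostat: microcanonical run).
#' @param max_events Stop after this many physical events.
#' @param max_time Stop at this reduced time.
#' @param sample_every Sampling interval in reduced time (frames + log rows).
#' @param seed Integer RNG seed for the engine stream.
#' @param validate Check state invariants before running (recommended).
#' @param use_cells Use cell lists for neighbour search (`FALSE` falls back to
#'   a single cell, i.e. all-pairs scanning; the dynamics are unchanged).
#' @return An object of class `dmd_run`: `trajectory` (a `dmd_trajectory`),
#'   `log` (data frame: time, kinetic, potential, t_star, n_hbonds, events),
#'   `counts` (events per kind), `final` (the end-of-run `dmd_state`).
#' @export
run_dmd <- function(state, table = default_interaction_table(), t_star = 0.18,
                    ghost_rate = 0, max_events = Inf, max_time = Inf,
                    sample_every = 5, seed = 1, validate = TRUE,
                    use_cells = TRUE) {
  stopifnot(inherits(state, "dmd_state"), !is.null(state$box))
  if (!is.finite(max_events) && !is.finite(max_time)) {
    stop("one of max_events or max_time must be finite")
  }
  arr <- engine_arrays(state, table)
  res <- run_dmd_cpp(
    state$pos, state$vel, state$beads$mass, arr$sigma,
    arr$peptide, arr$residue, arr$kind, arr$rcode,
    arr$bonds, arr$bond_lo, arr$bond_hi,
    arr$well_lambda, arr$well_eps,
    table$hbond$range, table$hbond$epsilon, unname(table$hbond$aux_min),
    arr$nbr_ca, arr$nbr_prev_co, arr$nbr_next_nh,
    as.integer(state$hb_partner) - 1L,
    state$box, t_star, ghost_rate, max_time, max_events, sample_every,
    arr$cell_range, as.integer(seed), validate, use_cells
  )
  frames <- lapply(seq_along(res$frames), function(k) {
    list(pos = res$frames[[k]], time = res$frame_times[k],
         hb_partner = as.integer(res$frame_partners[[k]]))
  })
  traj <- structure(
    list(frames = frames, beads = state$beads, bonds = state$bonds,
         box = state$box, n_peptides = state$n_peptides),
    class = "dmd_trajectory"
  )
  final <- state
  final$pos <- res$final_pos
  final$vel <- res$final_vel
  final$hb_partner <- as.integer(res$final_partner)
  final$time <- res$final_time
  log <- as.data.frame(res$samples)
  structure(
    list(trajectory = traj, log = log, counts = res$counts,
         events = res$events, final = final,
         params = list(t_star = t_star, ghost_rate = ghost_rate, seed = seed,
                       sample_every = sample_every)),
    class = "dmd_run"
  )
}

#' @export
print.dmd_run <- function(x, ...) {
  cat(sprintf("<dmd_run> %.0f events to t = %.2f, %d frames, %d H-bonds at end\n",
              x$events, x$final$time, length(x$trajectory$frames),
              count_hbonds(x$final)))
  invisible(x)
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf("<dmd_trajectory> %d frames x %d beads (%d peptides)\n",
              length(x$frames), nrow(x$beads), x$n_peptides))
  invisible(x)
}

#' Predict the next event for one bead pair
#'
#' Returns the earliest future discontinuity crossing for the pair given the
#' current relative position and velocity: hard-core contact, square-well
#' boundary (capture from outside, escape/bounce attempt from inside), bond
#' walls for bonded pairs, or hydrogen-bond association range crossing.
#' Exact quadratic-root solution; no time step.
#'
#' @param state A `dmd_state`.
#' @param i,j Bead indices.
#' @param table An `interaction_table`.
#' @return List `time` (reduced time from now; `Inf` if no event) and `kind`.
#' @export
pair_event_time <- function(state, i, j, table = default_interaction_table()) {
  stopifnot(i != j)
  dx <- pair_min_image(state$pos[j, ] - state$pos[i, ], state$box)
  dv <- state$vel[j, ] - state$vel[i, ]
  bidx <- which((state$bonds$i == i & state$bonds$j == j) |
                  (state$bonds$i == j & state$bonds$j == i))
  if (length(bidx) == 1) {
    lo <- state$bonds$length[bidx] * (1 - state$bonds$delta[bidx])
    hi <- state$bonds$length[bidx] * (1 + state$bonds$delta[bidx])
    out <- predict_pair_event_cpp(dx, dv, 0, -1, 0, TRUE, lo, hi, 0L, 0)
  } else {
    cl <- classify_pair(state, table, i, j)
    if (cl$excluded) return(list(time = Inf, kind = "none"))
    hb_mode <- if (!cl$hb_candidate) 0L
      else if (state$hb_partner[i] == j) 2L else 1L
    lam <- if (is.na(cl$lambda)) -1 else cl$lambda
    out <- predict_pair_event_cpp(dx, dv, cl$sigma, lam, cl$epsilon,
                                  FALSE, 0, 0, hb_mode, table$hbond$range)
  }
  out
}

#' Resolve a two-body event on a pair of beads
#'
#' Applies the momentum-conserving velocity update for a hard bounce
#' (core/bond wall), a well entry of depth `epsilon` (radial speed-up by
#' exactly `|epsilon|` of kinetic energy for an attractive well), or an
#' escape attempt (slow-down if the radial kinetic energy suffices, elastic
#' bounce otherwise).  Ghost events redraw one bead's velocity from the
#' Maxwell-Boltzmann distribution at `t_star`.
#'
#' @param state A `dmd_state`.
#' @param i Bead index (and `j` for two-body kinds).
#' @param j Second bead index, or `NA` for `"ghost"`.
#' @param kind `"bounce"`, `"capture"`, `"escape"` or `"ghost"`.
#' @param epsilon Well depth (reduced units, negative = attractive).
#' @param t_star Reduced temperature for ghost redraws.
#' @return List `state` (updated) and `outcome` (`"bounce"`, `"capture"`,
#'   `"escape"` or `"ghost"`; an energetically forbidden escape reports
#'   `"bounce"`).
#' @export
resolve_event <- function(state, i, j = NA, kind = c("bounce", "capture",
                                                     "escape", "ghost"),
                          epsilon = 0, t_star = 0.18) {
  kind <- match.arg(kind)
  if (kind == "ghost") {
    state$vel[i, ] <- stats::rnorm(3) * sqrt(t_star / state$beads$mass[i])
    return(list(state = state, outcome = "ghost"))
  }
  code <- c(bounce = 0L, capture = 1L, escape = 2L)[[kind]]
  out <- resolve_two_body_cpp(state$pos[i, ], state$pos[j, ],
                              state$vel[i, ], state$vel[j, ],
                              state$beads$mass[i], state$beads$mass[j],
                              code, epsilon)
  state$vel[i, ] <- out$vi
  state$vel[j, ] <- out$vj
  list(state = state, outcome = out$what)
}

#' Total reduced energy of a system state
#'
#' Kinetic energy plus the sum of engaged square-well depths (every
#' non-excluded sidechain pair inside its well contributes its depth;
#' every registered hydrogen bond contributes minus the hydrogen-bond
#' energy).  Direct O(N^2) evaluation, independent of the engine's
#' incremental bookkeeping.
#'
#' @param state A `dmd_state`.
#' @param table An `interaction_table`.
#' @return List `kinetic`, `potential`, `total` (reduced units).
#' @export
total_energy <- function(state, table = default_interaction_table()) {
  ke <- sum(0.5 * state$beads$mass * rowSums(state$vel^2))
  pe <- -table$hbond$epsilon * count_hbonds(state)
  ridx <- which(state$beads$kind == "R")
  if (length(ridx) >= 2) {
    b <- state$beads
    for (a in seq_along(ridx)[-length(ridx)]) {
      i <- ridx[a]
      js <- ridx[(a + 1):length(ridx)]
      ok <- b$peptide[js] != b$peptide[i] | abs(b$residue[js] - b$residue[i]) >= 3
      js <- js[ok]
      if (length(js) == 0) next
      d <- sweep(state$pos[js, , drop = FALSE], 2, state$pos[i, ], "-")
      if (!is.null(state$box)) d <- d - state$box * round(d / state$box)
      r <- sqrt(rowSums(d^2))
      for (k in seq_along(js)) {
        w <- pair_well(table, b$code[i], b$code[js[k]])
        if (w$epsilon != 0 && r[k] < w$lambda) pe <- pe + w$epsilon
      }
    }
  }
  list(kinetic = ke, potential = pe, total = ke + pe)
}

#' Instantaneous reduced temperature from the velocities
#'
#' \eqn{T^* = 2 KE / (3N)} (3N momentum degrees of freedom; bond walls are
#' stepwise potentials, not holonomic constraints).
#'
#' @param state A `dmd_state`.
#' @export
instantaneous_temperature <- function(state) {
  ke <- sum(0.5 * state$beads$mass * rowSums(state$vel^2))
  2 * ke / (3 * nrow(state$pos))
}

#' Number of registered hydrogen bonds
#' @param state A `dmd_state`.
#' @export
count_hbonds <- function(state) {
  sum(state$hb_partner > 0) / 2
}
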