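#' Per-pair link counts between peptides in one frame
#'
#' For every peptide pair: `n_hbonds` is the number of registered NH-CO
#' hydrogen bonds joining them; `n_hydrophobic` is the number of
#' hydrophobic-class sidechain bead pairs within their square-well range
#' (pairs without a tabulated well use `hydrophobic_cutoff`).
#'
#' @param frame A trajectory frame: `list(pos, hb_partner)`.
#' @param beads Bead metadata table (from a `dmd_trajectory` or `dmd_state`).
#' @param table An `interaction_table`.
#' @param box Periodic box length or `NULL`.
#' @param hydrophobic_cutoff Fallback contact distance (Angstrom).
#' @return Data frame `a`, `b`, `n_hbonds`, `n_hydrophobic` over all pairs.
#' @export
pairwise_links <- function(frame, beads, table = default_interaction_table(),
                           box = NULL, hydrophobic_cutoff = 5.5) {
  npep <- max(beads$peptide)
  nh <- matrix(0L, npep, npep)
  ph <- matrix(0L, npep, npep)
  # hydrogen bonds from the registry (count each NH->CO pair once)
  don <- which(beads$kind == "NH" & frame$hb_partner > 0)
  for (d in don) {
    a <- beads$peptide[d]; b <- beads$peptide[frame$hb_partner[d]]
    if (a != b) {
      lo <- min(a, b); hi <- max(a, b)
      nh[lo, hi] <- nh[lo, hi] + 1L
    }
  }
  # hydrophobic sidechain contacts
  reg <- residue_registry()
  hyb <- which(beads$kind == "R" & reg[beads$code, "class"] == "hydrophobic")
  if (length(hyb) >= 2) {
    hp <- beads$peptide[hyb]
    hx <- frame$pos[hyb, , drop = FALSE]
    for (ii in seq_len(length(hyb) - 1)) {
      jj <- (ii + 1):length(hyb)
      jj <- jj[hp[jj] != hp[ii]]
      if (length(jj) == 0) next
      d <- sweep(hx[jj, , drop = FALSE], 2, hx[ii, ], "-")
      if (!is.null(box)) d <- d - box * round(d / box)
      r <- sqrt(rowSums(d^2))
      for (kk in seq_along(jj)) {
        w <- pair_well(table, beads$code[hyb[ii]], beads$code[hyb[jj[kk]]])
        cut <- if (w$epsilon != 0) w$lambda else hydrophobic_cutoff
        if (r[kk] <= cut) {
          lo <- min(hp[ii], hp[jj[kk]]); hi <- max(hp[ii], hp[jj[kk]])
          ph[lo, hi] <- ph[lo, hi] + 1L
        }
      }
    }
  }
  idx <- which(upper.tri(nh), arr.ind = TRUE)
  data.frame(a = idx[, 1], b = idx[, 2],
             n_hbonds = nh[idx], n_hydrophobic = ph[idx])
}

#' Peptide connectivity graph of a frame
#'
#' Two peptides are connected when they share at least `hb_min` hydrogen
#' bonds or at least `phob_min` hydrophobic sidechain contacts.
#'
#' @param links Output of [pairwise_links()].
#' @param n_peptides Number of peptides.
#' @param hb_min Hydrogen-bond threshold (default 5).
#' @param phob_min Hydrophobic-contact threshold (default 2).
#' @return An igraph graph with vertex per peptide and edge attributes
#'   `n_hbonds`, `n_hydrophobic`.
#' @export
connectivity_graph <- function(links, n_peptides, hb_min = 5, phob_min = 2) {
  sel <- links$n_hbonds >= hb_min | links$n_hydrophobic >= phob_min
  el <- links[sel, , drop = FALSE]
  g <- igraph::make_empty_graph(n = n_peptides, directed = FALSE)
  if (nrow(el) > 0) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(el[, c("a", "b")]))))
    igraph::E(g)$n_hbonds <- el$n_hbonds
    igraph::E(g)$n_hydrophobic <- el$n_hydrophobic
  }
  g
}

#' Connected components of a connectivity graph
#' @param graph From [connectivity_graph()].
#' @return List of integer member vectors (sorted), one per cluster.
#' @export
clusters <- function(graph) {
  cmp <- igraph::components(graph)
  lapply(seq_len(cmp$no), function(k) sort(which(cmp$membership == k)))
}

#' Classify a cluster as free / oligomer / beta-sheet / beta-barrel
#'
#' The strand-adjacency subgraph keeps only links with at least `hb_min`
#' hydrogen bonds (the beta-ladder).  A single cycle visiting every member
#' (all degrees 2) is a beta-barrel — a sheet wrapped around with its first
#' and last strands hydrogen-bonded.  A single path covering every member
#' with at least `sheet_min` strands is a beta-sheet.  Everything else of
#' size > 1 is an oligomer; singletons are free peptides.
#'
#' @param component Integer member vector.
#' @param links [pairwise_links()] table for the frame.
#' @param hb_min Hydrogen-bond threshold (default 5).
#' @param sheet_min Minimum strands for a beta-sheet (default 4).
#' @return One of `"free"`, `"oligomer"`, `"beta_sheet"`, `"beta_barrel"`.
#' @export
classify_cluster <- function(component, links, hb_min = 5, sheet_min = 4) {
  n <- length(component)
  if (n == 1) return("free")
  el <- links[links$a %in% component & links$b %in% component &
                links$n_hbonds >= hb_min, c("a", "b"), drop = FALSE]
  ne <- nrow(el)
  if (ne > 0) {
    deg <- table(factor(c(el$a, el$b), levels = component))
    gg <- igraph::graph_from_data_frame(el, directed = FALSE,
                                        vertices = data.frame(name = component))
    connected <- igraph::components(gg)$no == 1
    if (connected && ne == n && all(deg == 2) && n >= 3) return("beta_barrel")
    if (connected && ne == n - 1 && all(deg <= 2) && n >= sheet_min) {
      return("beta_sheet")
    }
  }
  "oligomer"
}

#' Assembly kinetics time series over a trajectory
#'
#' For every frame: pairwise links, connectivity graph, cluster census and
#' classification; peptides in beta-sheet or beta-barrel clusters count as
#' fibrillar.  Clusters are tracked across consecutive frames by member
#' overlap greater than 50 percent, and class changes of tracked clusters
#' (e.g. a beta-barrel opening into a beta-sheet) are logged as transitions.
#'
#' @param trajectory A `dmd_trajectory` with at least one frame.
#' @param table An `interaction_table`.
#' @param hb_min,phob_min Connection thresholds (defaults 5 and 2).
#' @param sheet_min Minimum strands for a beta-sheet (default 4).
#' @return A `cluster_report`: `series` (data frame: time, n_free,
#'   n_oligomeric, n_fibrillar, n_clusters, n_fibril_clusters, total_hbonds),
#'   `frames` (per-frame cluster lists with classes), `transitions`
#'   (data frame: time, frame, from_class, to_class, members).
#' @export
kinetics_timeseries <- function(trajectory, table = default_interaction_table(),
                                hb_min = 5, phob_min = 2, sheet_min = 4) {
  stopifnot(inherits(trajectory, "dmd_trajectory"))
  if (length(trajectory$frames) == 0) stop("trajectory has no sampled frames")
  npep <- trajectory$n_peptides
  series <- list(); per_frame <- list(); transitions <- list()
  prev <- NULL
  for (f in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[f]]
    links <- pairwise_links(fr, trajectory$beads, table, trajectory$box)
    g <- connectivity_graph(links, npep, hb_min, phob_min)
    cls <- clusters(g)
    classes <- vapply(cls, classify_cluster, character(1),
                      links = links, hb_min = hb_min, sheet_min = sheet_min)
    sizes <- lengths(cls)
    fib <- classes %in% c("beta_sheet", "beta_barrel")
    series[[f]] <- data.frame(
      time = fr$time,
      n_free = sum(sizes[classes == "free"]),
      n_oligomeric = sum(sizes[classes == "oligomer"]),
      n_fibrillar = sum(sizes[fib]),
      n_clusters = sum(sizes > 1),
      n_fibril_clusters = sum(fib),
      total_hbonds = sum(fr$hb_partner > 0) / 2
    )
    now <- lapply(seq_along(cls), function(k) {
      list(members = cls[[k]], class = classes[k])
    })
    per_frame[[f]] <- now
    if (!is.null(prev)) {
      for (cur in now) {
        if (cur$class == "free") next
        for (old in prev$clusters) {
          if (old$class == "free") next
          ov <- length(intersect(cur$members, old$members))
          if (ov > 0.5 * max(length(cur$members), length(old$members)) &&
              old$class != cur$class) {
            transitions[[length(transitions) + 1]] <- data.frame(
              time = fr$time, frame = f,
              from_class = old$class, to_class = cur$class,
              members = paste(cur$members, collapse = "+"),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    prev <- list(clusters = now)
  }
  structure(
    list(series = do.call(rbind, series), frames = per_frame,
         transitions = if (length(transitions) > 0) do.call(rbind, transitions)
                       else data.frame(time = numeric(), frame = integer(),
                                       from_class = character(),
                                       to_class = character(),
                                       members = character())),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<cluster_report> %d frames; final: %d free, %d oligomeric, %d fibrillar; %d transition(s)\n",
              n, x$series$n_free[n], x$series$n_oligomeric[n],
              x$series$n_fibrillar[n], nrow(x$transitions)))
  invisible(x)
}

#' Time to reach a fraction of the final hydrogen-bond count
#'
#' Linear-interpolated first crossing of `frac` times the final H-bond count
#' in a run's sample log; used to compare assembly speed between systems.
#'
#' @param log A `dmd_run$log` data frame (columns `time`, `n_hbonds`).
#' @param frac Fraction of the final count (default 0.5).
#' @return Reduced time of first crossing (`NA` if never, e.g. no H-bonds).
#' @export
hbond_halftime <- function(log, frac = 0.5) {
  target <- frac * log$n_hbonds[nrow(log)]
  if (!is.finite(target) || target <= 0) return(NA_real_)
  k <- which(log$n_hbonds >= target)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1) return(log$time[1])
  t0 <- log$time[k - 1]; t1 <- log$time[k]
  y0 <- log$n_hbonds[k - 1]; y1 <- log$n_hbonds[k]
  if (y1 == y0) return(t1)
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}
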