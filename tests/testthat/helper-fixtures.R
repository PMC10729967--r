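# Shared fixtures and independent oracles for the test suite.

seq_6k <- catch_sequence("6K")
seq_6e <- catch_sequence("6E")
seq_6d <- catch_sequence("6D")
default_table <- default_interaction_table()

dist_between <- function(p, q) sqrt(sum((p - q)^2))

# Independent brute-force oracle: first crossing time of |dx + dv t| = target,
# located by scanning a fine time grid and polishing with uniroot.
scan_crossing_time <- function(dx, dv, target, t_max = 60, n_grid = 120000) {
  f <- function(t) {
    sqrt((dx[1] + t * dv[1])^2 + (dx[2] + t * dv[2])^2 +
           (dx[3] + t * dv[3])^2) - target
  }
  ts <- seq(0, t_max, length.out = n_grid)
  vals <- f(ts)
  k <- which(vals[-1] * vals[-length(vals)] < 0)[1]
  if (is.na(k)) {
    z <- which(vals == 0)[1]
    return(if (is.na(z)) Inf else ts[z])
  }
  stats::uniroot(function(t) f(t), c(ts[k], ts[k + 1]), tol = 1e-13)$root
}

# Random atomistic micro-structure with K donors and D/E acceptors.
random_polar_structure <- function(n_res, span = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (r in seq_len(n_res)) {
    code <- sample(c("K", "D", "E", "Q"), 1)
    base <- runif(3, 0, span)
    if (code == "K") {
      nz <- base
      for (h in 1:3) {
        dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        rows[[length(rows) + 1]] <- data.frame(
          chain = "A", resno = r, code = code, atom = paste0("HZ", h),
          elem = "H", x = nz[1] + 1.04 * dirv[1], y = nz[2] + 1.04 * dirv[2],
          z = nz[3] + 1.04 * dirv[3])
      }
      rows[[length(rows) + 1]] <- data.frame(chain = "A", resno = r,
                                             code = code, atom = "NZ",
                                             elem = "N", x = nz[1], y = nz[2],
                                             z = nz[3])
    } else if (code %in% c("D", "E")) {
      nm <- if (code == "D") c("OD1", "OD2") else c("OE1", "OE2")
      for (o in 1:2) {
        p <- base + runif(3, -1, 1)
        rows[[length(rows) + 1]] <- data.frame(chain = "A", resno = r,
                                               code = code, atom = nm[o],
                                               elem = "O", x = p[1], y = p[2],
                                               z = p[3])
      }
    } else {
      rows[[length(rows) + 1]] <- data.frame(chain = "A", resno = r,
                                             code = code, atom = "CB",
                                             elem = "C", x = base[1],
                                             y = base[2], z = base[3])
    }
  }
  atomistic_structure(do.call(rbind, rows))
}

# Exhaustive O(N^2) oracle for hydrogen bonds over explicit donor triples.
oracle_hbonds <- function(s, dcut, acut, donors, acceptors) {
  hits <- 0
  for (di in seq_len(nrow(s))) {
    for (k in seq_len(nrow(donors))) {
      if (s$code[di] != donors$code[k] || s$atom[di] != donors$h[k]) next
      heavy <- which(s$code == donors$code[k] & s$atom == donors$heavy[k] &
                       s$chain == s$chain[di] & s$resno == s$resno[di])
      if (length(heavy) != 1) next
      for (ai in seq_len(nrow(s))) {
        okacc <- any(acceptors$code == s$code[ai] & acceptors$atom == s$atom[ai])
        if (!okacc) next
        if (s$chain[ai] == s$chain[di] && s$resno[ai] == s$resno[di]) next
        h <- c(s$x[di], s$y[di], s$z[di])
        hv <- c(s$x[heavy], s$y[heavy], s$z[heavy])
        a <- c(s$x[ai], s$y[ai], s$z[ai])
        dd <- sqrt(sum((a - h)^2))
        if (dd > dcut) next
        v1 <- hv - h; v2 <- a - h
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= acut) hits <- hits + 1
      }
    }
  }
  hits
}

# Exhaustive contact-count oracle by residue-code pair.
oracle_contact_map <- function(s, cutoff) {
  codes <- sort(unique(s$code))
  m <- matrix(0L, length(codes), length(codes), dimnames = list(codes, codes))
  n <- nrow(s)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (s$chain[i] == s$chain[j] && s$resno[i] == s$resno[j]) next
    dd <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
    if (dd <= cutoff) {
      a <- s$code[i]; b <- s$code[j]
      m[a, b] <- m[a, b] + 1L
      if (a != b) m[b, a] <- m[b, a] + 1L
    }
  }
  m
}

# Transitive-closure component oracle over an edge list.
oracle_components <- function(n, edges) {
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        lab[lab == lab[a] | lab == lab[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(n), lab), sort))
}

# Pairwise-link table with prescribed (a, b, n_hbonds, n_hydrophobic) rows.
make_links <- function(n, triples) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  df <- data.frame(a = idx[, 1], b = idx[, 2], n_hbonds = 0L,
                   n_hydrophobic = 0L)
  for (tr in triples) {
    row <- which(df$a == min(tr[1], tr[2]) & df$b == max(tr[1], tr[2]))
    df$n_hbonds[row] <- tr[3]
    df$n_hydrophobic[row] <- tr[4]
  }
  df
}

# Small thermalised random-coil system reused across engine tests.
small_system <- function(n_plus = 2, n_minus = 2, box = 70, seed = 42) {
  random_coil_box(seq_6k, seq_6e, n_plus, n_minus, box, seed = seed)
}
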