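aa1to3 <- function(code) {
  m <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
         Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
  unname(m[code])
}
aa3to1 <- function(resid) {
  m <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
         GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
  unname(m[toupper(resid)])
}

#' Read a PDB file into an atomistic structure table
#'
#' Uses bio3d for parsing after a line-level sanity check; a truncated ATOM
#' record is reported with its line number.  Both conventional atomistic
#' files and the package's four-bead dialect (atom names N/CA/C/R, one chain
#' per peptide) read back with this function.
#'
#' @param path PDB file path.
#' @return An `atomistic_structure`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- grepl("^(ATOM|HETATM)", lines)
  short <- which(at & nchar(lines) < 54)
  if (length(short) > 0) {
    stop(sprintf("malformed ATOM record at line %d of %s (only %d characters)",
                 short[1], path, nchar(lines[short[1]])))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  code <- aa3to1(a$resid)
  if (any(is.na(code))) {
    stop("unknown residue name(s): ",
         paste(unique(a$resid[is.na(code)]), collapse = ", "))
  }
  atomistic_structure(data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, code = code, atom = a$elety,
    elem = ifelse(is.na(a$elesy) | a$elesy == "", substr(a$elety, 1, 1), a$elesy),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Write a structure or system as PDB
#'
#' The `"atomistic"` dialect writes an `atomistic_structure` table verbatim.
#' The `"four_bead"` dialect writes a `sheet_model` or `dmd_state` with atom
#' names N, CA, C, R, standard three-letter residue names and one chain per
#' peptide, so files stay loadable by common viewers.
#'
#' @param x An `atomistic_structure`, `sheet_model` or `dmd_state`.
#' @param path Output path.
#' @param dialect `"atomistic"` or `"four_bead"`.
#' @return The path, invisibly.
#' @export
write_pdb <- function(x, path, dialect = c("atomistic", "four_bead")) {
  dialect <- match.arg(dialect)
  if (dialect == "atomistic") {
    if (!inherits(x, "atomistic_structure")) {
      stop("atomistic dialect requires an atomistic_structure")
    }
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(x[, c("x", "y", "z")]))),
                     resno = x$resno, resid = aa1to3(x$code),
                     chain = x$chain, elety = x$atom, elesy = x$elem)
    return(invisible(path))
  }
  if (inherits(x, "sheet_model")) {
    b <- sheet_model_beads(x)
  } else if (inherits(x, "dmd_state")) {
    b <- state_beads_table(x)
  } else {
    stop("four_bead dialect requires a sheet_model or dmd_state")
  }
  chains <- c(LETTERS, letters, 0:9)
  elety <- c(NH = "N", CA = "CA", CO = "C", R = "R")[b$kind]
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(b[, c("x", "y", "z")]))),
                   resno = b$residue, resid = aa1to3(b$code),
                   chain = chains[(b$peptide - 1) %% length(chains) + 1],
                   elety = elety,
                   elesy = substr(elety, 1, 1))
  invisible(path)
}

state_beads_table <- function(state) {
  data.frame(peptide = state$beads$peptide, residue = state$beads$residue,
             kind = state$beads$kind, code = state$beads$code,
             x = state$pos[, 1], y = state$pos[, 2], z = state$pos[, 3],
             stringsAsFactors = FALSE)
}

#' Convert a four-bead object to an atomistic-structure table
#'
#' Bead kinds map to atom names N/CA/C/R; one chain per peptide.  This is the
#' carrier the contact-map and grouping analyses consume.
#'
#' @param x A `sheet_model` or `dmd_state`.
#' @return An `atomistic_structure`.
#' @export
as_structure <- function(x) {
  b <- if (inherits(x, "sheet_model")) sheet_model_beads(x) else state_beads_table(x)
  chains <- c(LETTERS, letters, 0:9)
  elety <- c(NH = "N", CA = "CA", CO = "C", R = "R")[b$kind]
  atomistic_structure(data.frame(
    chain = chains[(b$peptide - 1) %% length(chains) + 1],
    resno = b$residue, code = b$code, atom = elety,
    elem = substr(elety, 1, 1), x = b$x, y = b$y, z = b$z,
    stringsAsFactors = FALSE))
}

#' Write a kinetics time series (or any data frame) as CSV
#'
#' Comma-separated, UTF-8, "." decimal; a leading comment line states that
#' times are in reduced units.  An empty series produces a header-only file.
#'
#' @param x A `cluster_report`, `dmd_run` log, or data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(x, path) {
  df <- if (inherits(x, "cluster_report")) x$series
        else if (inherits(x, "dmd_run")) x$log
        else as.data.frame(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# time in reduced units (tau = sqrt(amu A^2 / epsilon_HB))", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read back a time series written by [write_timeseries()]
#' @param path CSV path.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read a contact map as a labelled CSV matrix
#'
#' @param map A `contact_map`.
#' @param path CSV path.
#' @return `write_contactmap`: the path, invisibly; `read_contactmap`: the
#'   `contact_map` (cutoff recovered from the header comment).
#' @export
write_contactmap <- function(map, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# contact map, cutoff %.6g Angstrom", attr(map, "cutoff")), con)
  utils::write.csv(as.data.frame(unclass(map)), con, row.names = TRUE)
  invisible(path)
}

#' @rdname write_contactmap
#' @export
read_contactmap <- function(path) {
  first <- readLines(path, n = 1)
  cutoff <- as.numeric(sub(".*cutoff ([0-9.eE+-]+) Angstrom.*", "\\1", first))
  df <- utils::read.csv(path, comment.char = "#", row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  attr(m, "cutoff") <- cutoff
  class(m) <- c("contact_map", class(m))
  m
}

#' Write / read a trajectory as XYZ with metadata comments
#'
#' One XYZ block per frame; the comment line carries the frame time, the box
#' length and the hydrogen-bond registry (`hb=donor-acceptor,...` in bead
#' indices), so a read-back trajectory supports the kinetics analyses.
#' Bead labels are the atom names of the four-bead dialect.
#'
#' @param traj A `dmd_trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  lab <- c(NH = "N", CA = "CA", CO = "C", R = "R")[traj$beads$kind]
  n <- nrow(traj$beads)
  for (fr in traj$frames) {
    writeLines(as.character(n), con)
    don <- which(traj$beads$kind == "NH" & fr$hb_partner > 0)
    hb <- if (length(don) > 0) {
      paste(sprintf("%d-%d", don, fr$hb_partner[don]), collapse = ",")
    } else ""
    writeLines(sprintf("t= %.9g box= %.9g hb= %s", fr$time,
                       ifelse(is.null(traj$box), -1, traj$box), hb), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", lab,
                       fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @param beads Bead metadata table matching the written system.
#' @export
read_trajectory <- function(path, beads) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  k <- 1; box <- NULL
  while (k <= length(lines)) {
    n <- as.integer(lines[k])
    meta <- lines[k + 1]
    tm <- as.numeric(sub("^t= ([0-9.eE+-]+) .*", "\\1", meta))
    bx <- as.numeric(sub(".*box= ([0-9.eE+-]+) .*", "\\1", meta))
    if (bx > 0) box <- bx
    hbs <- sub(".*hb= ?", "", meta)
    partner <- integer(n)
    if (nchar(hbs) > 0) {
      pr <- do.call(rbind, strsplit(strsplit(hbs, ",")[[1]], "-"))
      pr <- matrix(as.integer(pr), ncol = 2)
      partner[pr[, 1]] <- pr[, 2]
      partner[pr[, 2]] <- pr[, 1]
    }
    rows <- lines[(k + 2):(k + 1 + n)]
    sp <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), function(v) {
      as.numeric(v[2:4])
    }))
    frames[[length(frames) + 1]] <- list(pos = sp, time = tm, hb_partner = partner)
    k <- k + 2 + n
  }
  structure(list(frames = frames, beads = beads, bonds = NULL, box = box,
                 n_peptides = max(beads$peptide)),
            class = "dmd_trajectory")
}

fnv1a <- function(s) {
  h <- 16777619
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Standard metadata block embedded in package outputs
#' @param seed Seed used for the run.
#' @param config Any serialisable configuration object.
#' @return List with package version, seed and a config hash.
#' @export
run_metadata <- function(seed, config = list()) {
  list(package = "catchdmd",
       version = as.character(utils::packageVersion("catchdmd")),
       seed = seed,
       config_hash = fnv1a(yaml::as.yaml(config)))
}
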