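#' Residue registry for the four-bead peptide model
#'
#' One row per standard amino acid: one-letter code, physicochemical class,
#' sidechain mass (residue mass minus the NH + CA + CO backbone beads),
#' hard-core diameter of the sidechain bead, nominal CA--R bond length,
#' sidechain "reach" (extended tip extent measured from the backbone plane,
#' used by the bilayer stacking constructor), and the atomistic donor /
#' acceptor atom names used for salt-bridge detection (ammonium hydrogens on
#' lysine; carboxylate oxygens on aspartate / glutamate).
#'
#' Glycine carries no sidechain bead (`has_sidechain = FALSE`).
#'
#' @return A data frame with one row per residue, keyed by `code`.
#' @export
residue_registry <- function() {
  reg <- data.frame(
    code = c("A","R","N","D","C","E","Q","G","H","I",
             "L","K","M","F","P","S","T","W","Y","V"),
    class = c("hydrophobic","cationic","polar","anionic","hydrophobic",
              "anionic","polar","polar","cationic","hydrophobic",
              "hydrophobic","cationic","hydrophobic","hydrophobic","polar",
              "polar","polar","hydrophobic","polar","hydrophobic"),
    sidechain_mass = c(15.04, 100.15, 58.06, 59.04, 47.10,
                       73.07, 72.09, NA, 81.10, 57.12,
                       57.12, 72.13, 75.15, 91.13, 41.07,
                       31.03, 45.06, 130.17, 107.13, 43.09),
    sigma = c(3.4, 4.8, 4.2, 4.0, 3.6,
              4.4, 4.4, 3.2, 4.6, 4.4,
              4.4, 4.6, 4.6, 4.5, 4.0,
              3.4, 3.8, 5.0, 4.8, 4.0),
    ca_r_length = c(1.5, 4.0, 2.3, 2.2, 2.1,
                    2.8, 2.8, NA, 3.1, 2.3,
                    2.6, 3.5, 2.9, 3.4, 1.9,
                    1.9, 1.9, 3.9, 3.8, 2.0),
    has_sidechain = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                      TRUE, TRUE, FALSE, TRUE, TRUE,
                      TRUE, TRUE, TRUE, TRUE, TRUE,
                      TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  # Extended sidechain reach beyond the backbone plane.  K/E/D values are the
  # extended-rotamer extents used by the stacked-bilayer constructor; for the
  # remaining residues the CG estimate (bond length + bead radius) is used.
  reach <- reg$ca_r_length + reg$sigma / 2
  reach[reg$code == "K"] <- 6.40
  reach[reg$code == "E"] <- 5.40
  reach[reg$code == "D"] <- 3.30
  reach[reg$code == "G"] <- 1.0
  reg$reach <- reach
  rownames(reg) <- reg$code
  reg
}

#' Atom-name lists used in atomistic salt-bridge detection
#'
#' @param code One-letter residue code.
#' @return List with `donor_atoms` (polar hydrogens) and `acceptor_atoms`
#'   (carboxylate oxygens); empty vectors when the residue has neither.
#' @export
residue_polar_atoms <- function(code) {
  switch(code,
    K = list(donor_atoms = c("HZ1", "HZ2", "HZ3"), acceptor_atoms = character()),
    D = list(donor_atoms = character(), acceptor_atoms = c("OD1", "OD2")),
    E = list(donor_atoms = character(), acceptor_atoms = c("OE1", "OE2")),
    list(donor_atoms = character(), acceptor_atoms = character())
  )
}

#' Parse a peptide sequence from a one-letter string
#'
#' Builds a peptide sequence object carrying per-residue classes and the
#' derived net charge (number of cationic minus number of anionic residues).
#' Terminal caps neutralise the backbone termini and are folded into the
#' terminal backbone beads; they add no extra beads or charge.
#'
#' @param s One-letter amino-acid string, e.g. `"KQKFKFKFKQK"`.
#' @param caps Length-2 character vector `(N-terminal, C-terminal)` from
#'   `{"acetyl", "amide", "free"}`.
#' @param label Optional label; defaults to the sequence string.
#' @return An object of class `catch_seq` with fields `residues`, `classes`,
#'   `net_charge`, `caps`, `label`.
#' @examples
#' sequence_from_string("KQKFKFKFKQK")$net_charge  # +6
#' sequence_from_string("EQEFEFEFEQE")$net_charge  # -6
#' @export
sequence_from_string <- function(s, caps = c("acetyl", "amide"), label = s) {
  stopifnot(is.character(s), length(s) == 1, nchar(s) >= 2)
  caps <- match.arg(caps, c("acetyl", "amide", "free"), several.ok = TRUE)
  if (length(caps) == 1) caps <- rep(caps, 2)
  reg <- residue_registry()
  codes <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(codes, reg$code)
  if (length(bad) > 0) {
    stop("invalid one-letter residue code(s): ", paste(unique(bad), collapse = ", "))
  }
  classes <- reg[codes, "class"]
  net <- sum(classes == "cationic") - sum(classes == "anionic")
  structure(
    list(residues = codes, classes = classes, net_charge = net,
         caps = caps, label = label),
    class = "catch_seq"
  )
}

#' @export
print.catch_seq <- function(x, ...) {
  cat(sprintf("<catch_seq> %s (%d residues, net charge %+d, caps %s/%s)\n",
              paste(x$residues, collapse = ""), length(x$residues),
              x$net_charge, x$caps[1], x$caps[2]))
  invisible(x)
}

#' @export
length.catch_seq <- function(x) length(x$residues)

#' Preset CATCH sequences
#'
#' The cationic 11-mer KQKFKFKFKQK and its anionic partners EQEFEFEFEQE
#' (glutamate) and DQDFDFDFDQD (aspartate), all following the alternating
#' charged/hydrophobic CQCFCFCFCQC pattern, acetyl/amide capped.
#'
#' @param name One of `"6K"`, `"6E"`, `"6D"`.
#' @return A `catch_seq`.
#' @export
catch_sequence <- function(name = c("6K", "6E", "6D")) {
  name <- match.arg(name)
  s <- switch(name,
    "6K" = "KQKFKFKFKQK",
    "6E" = "EQEFEFEFEQE",
    "6D" = "DQDFDFDFDQD")
  sequence_from_string(s, label = paste0("CATCH(", name, ifelse(name == "6K", "+", "-"), ")"))
}
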