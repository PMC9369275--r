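#' @include AllClasses.R
NULL

# Monoisotopic residue masses (Da) of the 20 standard amino acids, i.e. the
# mass each residue contributes inside a peptide chain (free amino acid minus
# one water). Values to 1e-5 Da.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00918, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04048,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.MASS_WATER  <- 18.010565   # H2O
.MASS_ACETYL <- 42.010565   # + C2H2O on the N terminus
.MASS_AMIDE  <- -0.9840156  # C-terminal OH -> NH2

#' Parse a peptide notation string
#'
#' Accepts plain one-letter sequences and the synthesis notation used for
#' terminally modified peptides: an `Ace-` prefix marks an N-terminal acetyl
#' group, an `-OH` suffix a free C-terminal acid (the default), and `-NH2` a
#' C-terminal amide. Whitespace inside the sequence is ignored (printed
#' sequences are often line-wrapped) and parsing is case-insensitive.
#'
#' @param text A single notation string, e.g. `"TYFAVLM"` or
#'   `"Ace-LVLAMWKVGFFKRNRPP LEEDDEEGQ-OH"`.
#' @return A [PeptideSequence-class] object.
#' @examples
#' parsePeptide("TYFAVLM")
#' parsePeptide("Ace-LVLAMWKVGFFKRNRPP LEEDDEEGQ-OH")
#' @export
parsePeptide <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("peptide notation must be a single non-empty string")
  s <- trimws(text)
  nTerm <- "free"
  if (grepl("^ace-", s, ignore.case = TRUE)) {
    nTerm <- "acetyl"
    s <- sub("^ace-", "", s, ignore.case = TRUE)
  }
  cTerm <- "acid"
  if (grepl("-nh2$", s, ignore.case = TRUE)) {
    cTerm <- "amide"
    s <- sub("-nh2$", "", s, ignore.case = TRUE)
  } else if (grepl("-oh$", s, ignore.case = TRUE)) {
    s <- sub("-oh$", "", s, ignore.case = TRUE)
  }
  s <- gsub("[[:space:]]", "", s)
  res <- toupper(strsplit(s, "")[[1]])
  if (length(res) == 0L) stop("peptide notation contains no residues")
  bad <- !res %in% names(.RESIDUE_MASS)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown residue '%s' at position %d", res[i], i))
  }
  new("PeptideSequence", residues = res, nTerm = nTerm, cTerm = cTerm)
}

#' @describeIn parsePeptide Number of residues.
#' @param x A `PeptideSequence`.
#' @export
setMethod("length", "PeptideSequence", function(x) length(x@residues))

#' Theoretical monoisotopic mass of a peptide
#'
#' Sum of the monoisotopic residue masses plus one water for the intact
#' chain. With `includeMods = TRUE` (the default) terminal modifications are
#' applied: an N-terminal acetyl adds 42.010565 Da and a C-terminal amide
#' replaces the acid (-0.984016 Da). With `includeMods = FALSE` the mass of
#' the unmodified linear peptide (free N- and C-termini) is returned, which
#' is the convention used for the assay's reported theoretical masses (see
#' [printedMass()]).
#'
#' @param p A [PeptideSequence-class].
#' @param includeMods Apply terminal modifications?
#' @return Mass in daltons.
#' @examples
#' monoisotopicMass(parsePeptide("G"))  # glycine: 75.032 Da
#' @export
monoisotopicMass <- function(p, includeMods = TRUE) {
  stopifnot(is(p, "PeptideSequence"))
  m <- sum(.RESIDUE_MASS[p@residues]) + .MASS_WATER
  if (isTRUE(includeMods)) {
    if (p@nTerm == "acetyl") m <- m + .MASS_ACETYL
    if (p@cTerm == "amide") m <- m + .MASS_AMIDE
  }
  unname(m)
}

#' Integer-dalton theoretical mass as printed in assay reports
#'
#' The reported theoretical monoisotopic masses of synthesis-grade peptides
#' are conventionally stated for the unmodified linear chain and truncated to
#' whole daltons; this helper reproduces that convention.
#'
#' @inheritParams monoisotopicMass
#' @return Integer daltons (truncated toward zero).
#' @export
printedMass <- function(p, includeMods = FALSE) {
  trunc(monoisotopicMass(p, includeMods = includeMods))
}

#' Count substitutions between two equal-length peptides
#'
#' Hamming distance: the number of aligned positions at which the residues
#' differ. Terminal modifications are ignored.
#'
#' @param a,b [PeptideSequence-class] objects of equal length.
#' @return Integer count.
#' @examples
#' countMutations(parsePeptide("AAA"), parsePeptide("AAG"))
#' @export
countMutations <- function(a, b) {
  stopifnot(is(a, "PeptideSequence"), is(b, "PeptideSequence"))
  if (length(a@residues) != length(b@residues))
    stop("sequences must have equal length to count substitutions")
  sum(a@residues != b@residues)
}

#' Tabulate peptides from notation strings or a FASTA file
#'
#' @param x Character vector of notation strings, optionally named, or the
#'   path to a single FASTA file of amino-acid sequences (requires the
#'   Biostrings package).
#' @return A data.frame with one row per peptide: name, sequence, length,
#'   terminal modifications, monoisotopic mass with and without
#'   modifications, and the integer printed-mass convention.
#' @export
peptideTable <- function(x) {
  if (length(x) == 1L && file.exists(x) && !grepl("^[A-Za-z ]+$", x)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA requires the Biostrings package")
    aa <- Biostrings::readAAStringSet(x)
    x <- stats::setNames(as.character(aa), names(aa))
  }
  if (is.null(names(x))) names(x) <- paste0("peptide", seq_along(x))
  rows <- lapply(seq_along(x), function(i) {
    p <- parsePeptide(x[[i]])
    data.frame(name = names(x)[i],
               sequence = paste(p@residues, collapse = ""),
               length = length(p), nTerm = p@nTerm, cTerm = p@cTerm,
               mass = monoisotopicMass(p, includeMods = TRUE),
               massUnmodified = monoisotopicMass(p, includeMods = FALSE),
               printedMass = printedMass(p))
  })
  do.call(rbind, rows)
}
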