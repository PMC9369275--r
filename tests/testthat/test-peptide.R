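# Independent oracle: residue masses recomputed from atomic compositions and
# monoisotopic element masses, so the package's hand-entered residue table is
# checked against first principles rather than against itself.
elementMass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069)

residueFormula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

formulaMass <- function(f) sum(elementMass[names(f)] * f)

oracleMass <- function(p) {
  sum(vapply(p@residues, function(r) formulaMass(residueFormula[[r]]),
             numeric(1))) + formulaMass(c(H = 2, O = 1))
}

test_that("residue mass table matches atomic compositions", {
  tab <- thromboflow:::.RESIDUE_MASS
  for (r in names(tab))
    expect_equal(unname(tab[r]), formulaMass(residueFormula[[r]]),
                 tolerance = 1e-6, label = r)
  expect_equal(thromboflow:::.MASS_WATER, formulaMass(c(H = 2, O = 1)),
               tolerance = 1e-7)
  # acetylation adds C2H2O; amidation swaps OH for NH2
  expect_equal(thromboflow:::.MASS_ACETYL,
               formulaMass(c(C = 2, H = 2, O = 1)), tolerance = 1e-7)
  expect_equal(thromboflow:::.MASS_AMIDE,
               formulaMass(c(N = 1, H = 1)) - formulaMass(c(O = 1)),
               tolerance = 1e-7)
})

test_that("parsePeptide handles notation, whitespace and case", {
  p <- parsePeptide(PCIB)
  expect_s4_class(p, "PeptideSequence")
  expect_identical(length(p), 26L)
  expect_identical(p@nTerm, "acetyl")
  expect_identical(p@cTerm, "acid")
  expect_identical(paste(p@residues, collapse = ""),
                   "LVLAMWKVGFFKRNRPPLEEDDEEGQ")
  expect_identical(parsePeptide("ace-tyfavlm-nh2")@cTerm, "amide")
  expect_identical(parsePeptide("  T Y F A V L M  ")@residues,
                   parsePeptide(PGRP)@residues)
  expect_identical(length(parsePeptide(PGRP)), 7L)
})

test_that("parsePeptide rejects malformed input with position info", {
  expect_error(parsePeptide(""), "non-empty")
  expect_error(parsePeptide(c("AA", "GG")), "single")
  expect_error(parsePeptide("Ace--OH"), "no residues")
  expect_error(parsePeptide("AAXGG"), "unknown residue 'X' at position 3")
  expect_error(parsePeptide("AAB"), "position 3")
})

test_that("monoisotopic masses agree with the composition oracle", {
  expect_equal(monoisotopicMass(parsePeptide("G")),
               formulaMass(c(C = 2, H = 5, N = 1, O = 2)), tolerance = 1e-6)
  for (s in c(PCIB, PCIBM, PGRP, "ACDEFGHIKLMNPQRSTVWY")) {
    p <- parsePeptide(s)
    expect_equal(monoisotopicMass(p, includeMods = FALSE), oracleMass(p),
                 tolerance = 1e-5, label = s)
  }
})

test_that("terminal modifications are applied only when requested", {
  p <- parsePeptide("Ace-GAV-NH2")
  base <- monoisotopicMass(p, includeMods = FALSE)
  expect_equal(monoisotopicMass(p, includeMods = TRUE),
               base + formulaMass(c(C = 2, H = 2, O = 1)) +
                 formulaMass(c(N = 1, H = 1)) - formulaMass(c(O = 1)),
               tolerance = 1e-7)
  free <- parsePeptide("GAV")
  expect_equal(monoisotopicMass(free, TRUE), monoisotopicMass(free, FALSE))
})

test_that("printed integer masses reproduce the reported values", {
  expect_identical(printedMass(parsePeptide(PCIB)), 3102)
  expect_identical(printedMass(parsePeptide(PCIBM)), 3284)
})

test_that("countMutations gives the published substitution count", {
  expect_identical(countMutations(parsePeptide(PCIB), parsePeptide(PCIBM)), 5L)
  expect_identical(countMutations(parsePeptide("AAA"), parsePeptide("AAA")), 0L)
  expect_error(countMutations(parsePeptide("AAA"), parsePeptide("AA")),
               "equal length")
})

test_that("peptideTable works on strings and FASTA", {
  tab <- peptideTable(c(pCIB = PCIB, pCIBm = PCIBM, pGRP = PGRP))
  expect_identical(tab$length, c(26L, 26L, 7L))
  expect_identical(tab$printedMass, c(3102, 3284, printedMass(parsePeptide(PGRP))))
  expect_identical(tab$nTerm, c("acetyl", "acetyl", "free"))
  expect_true(all(tab$mass[1:2] > tab$massUnmodified[1:2]))

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">pGRP", "TYFAVLM"), fa)
  tab2 <- peptideTable(fa)
  expect_identical(tab2$name, "pGRP")
  expect_identical(tab2$length, 7L)
  expect_equal(tab2$mass, monoisotopicMass(parsePeptide(PGRP)))
})
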