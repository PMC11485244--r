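test_that("segment masses follow the standard residue-mass table", {
  g <- segmentSpec("s", 1, 1)
  expect_equal(segmentMass(g, c(s = "G")), 57.0519 + 18.01528, tolerance = 1e-6)
  expect_equal(segmentMass(g, c(s = "G"), mode = "monoisotopic"),
               57.02146 + 18.010565, tolerance = 1e-6)
  ## carbamidomethyl-Cys fixed modification
  cseg <- segmentSpec("s", 1, 2)
  expect_equal(segmentMass(cseg, c(s = "CC"), camCys = TRUE) -
                 segmentMass(cseg, c(s = "CC")), 2 * 57.0513,
               tolerance = 1e-6)
  expect_error(segmentMass(segmentSpec("s", 1, 3), c(s = "GXB")),
               "non-standard")
  expect_error(segmentMass(segmentSpec("s", 2, 9), c(s = "GGG")), "outside")
  expect_error(segmentMass(segmentSpec("other", 1, 2), c(s = "GGG")),
               "does not match")
})

test_that("mass is additive over contiguous splits up to the shared waters", {
  set.seed(17)
  w <- waterMass()
  for (rep in 1:15) {
    seqc <- paste(sample(AA, sample(10:60, 1), replace = TRUE), collapse = "")
    L <- nchar(seqc)
    k <- sample(2:4, 1)
    cuts <- sort(sample(1:(L - 1), k - 1))
    bounds <- cbind(c(1, cuts + 1), c(cuts, L))
    total <- segmentMass(segmentSpec("s", 1, L), c(s = seqc))
    parts <- sum(apply(bounds, 1, function(b)
      segmentMass(segmentSpec("s", b[1], b[2]), c(s = seqc))))
    expect_equal(parts - (k - 1) * w, total, tolerance = 1e-9)
  }
})

test_that("the filament fold regions have their reported masses", {
  fr <- foldRegionSequences()
  anxa <- fr$ANXA11; tdp <- fr$TDP43
  m_anxa <- segmentMass(segmentSpec("ANXA11", 39, 74), anxa$sequence,
                        offset = anxa$offset)
  expect_equal(m_anxa / 1000, 3.8, tolerance = 0.02)
  m_tdp282 <- segmentMass(segmentSpec("TDP43", 282, 345), tdp$sequence,
                          offset = tdp$offset)
  expect_equal(m_tdp282 / 1000, 6.2, tolerance = 0.02)
  m_tdp284 <- segmentMass(segmentSpec("TDP43", 284, 345), tdp$sequence,
                          offset = tdp$offset)
  expect_equal(m_tdp284 / 1000, 6.0, tolerance = 0.02)
})

test_that("residue counting is exact over inclusive spans", {
  expect_equal(countResidue(segmentSpec("s", 1, 3), c(s = "PPP"), "P"), 3L)
  expect_error(countResidue(segmentSpec("s", 1, 3), c(s = "PPP"), "p"),
               "single standard")
  fr <- foldRegionSequences()
  expect_equal(countResidue(segmentSpec("ANXA11", 39, 74),
                            fr$ANXA11$sequence, "P",
                            offset = fr$ANXA11$offset), 1L)
  expect_equal(countResidue(segmentSpec("ANXA11", 37, 70),
                            fr$ANXA11$sequence, "P",
                            offset = fr$ANXA11$offset), 0L)
})

test_that("fragment boundaries minimize the deviation from a target mass", {
  ## cumulative-sum oracle on pentaglycine: masses 75.07, 132.12, 189.17, ...
  b <- fragmentBoundaryFromMass(c(s = "GGGGG"), 150)
  expect_equal(b$index, 2L)
  expect_equal(b$mass, 2 * 57.0519 + 18.01528, tolerance = 1e-4)

  full <- segmentMass(segmentSpec("s", 1, 5), c(s = "GGGGG"))
  expect_equal(fragmentBoundaryFromMass(c(s = "GGGGG"), full)$index, 5L)
  expect_error(fragmentBoundaryFromMass(c(s = "GGGGG"), 10), "outside")
  expect_error(fragmentBoundaryFromMass(c(s = "GGGGG"), 1e6), "outside")

  ## C-terminal fragments: target = mass of the last k residues
  set.seed(23)
  seqc <- paste(sample(AA, 40, replace = TRUE), collapse = "")
  for (k in c(5, 17, 33)) {
    target <- segmentMass(segmentSpec("s", 41 - k, 40), c(s = seqc))
    expect_equal(fragmentBoundaryFromMass(c(s = seqc), target, "C")$index,
                 41L - k)
  }

  ## monotone in the target mass
  targets <- seq(500, 4000, by = 250)
  idx <- vapply(targets, function(t)
    fragmentBoundaryFromMass(c(s = seqc), t)$index, numeric(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("chymotryptic digestion enumerates missed-cleavage peptides", {
  ## whole chain when no specificity residue occurs
  ps <- chymotrypticPeptides("AGAGAG", maxMissed = 3)
  expect_equal(nrow(peptideTable(ps)), 1L)
  expect_equal(peptideTable(ps)$sequence, "AGAGAG")

  ps0 <- chymotrypticPeptides("AFGAWG", maxMissed = 0)
  expect_setequal(peptideTable(ps0)$sequence, c("AF", "GAW", "G"))
  ps1 <- chymotrypticPeptides("AFGAWG", maxMissed = 1)
  expect_setequal(peptideTable(ps1)$sequence,
                  c("AF", "GAW", "G", "AFGAW", "GAWG"))

  ## proline suppresses the preceding cleavage site
  expect_equal(peptideTable(chymotrypticPeptides("AFPG", maxMissed = 0))$sequence,
               "AFPG")
  expect_setequal(
    peptideTable(chymotrypticPeptides("AFPG", maxMissed = 0, noP = FALSE))$sequence,
    c("AF", "PG"))
})

test_that("digestion equals brute-force interval enumeration for random chains", {
  set.seed(29)
  for (rep in 1:12) {
    seqc <- paste(sample(AA, sample(15:60, 1), replace = TRUE), collapse = "")
    for (mm in 0:3) {
      got <- peptideTable(chymotrypticPeptides(seqc, maxMissed = mm))
      want <- oracleDigest(seqc, mm)
      expect_equal(got[, c("start", "end", "missed")],
                   want, ignore_attr = TRUE)
      ## reported masses match segmentMass on the same spans
      expect_equal(got$mass,
                   vapply(seq_len(nrow(got)), function(i)
                     segmentMass(segmentSpec("seq1", got$start[i], got$end[i]),
                                 c(seq1 = seqc)), numeric(1)),
                   tolerance = 1e-9)
    }
    ## zero-missed peptides tile the chain exactly
    p0 <- peptideTable(chymotrypticPeptides(seqc, maxMissed = 0))
    expect_equal(paste(p0$sequence[order(p0$start)], collapse = ""), seqc)
  }
})

test_that("peptide length filters and numbering offsets are honoured", {
  ps <- chymotrypticPeptides("AFGAWG", maxMissed = 1, minLength = 3)
  expect_true(all(nchar(peptideTable(ps)$sequence) >= 3))
  ps2 <- chymotrypticPeptides("AFGAWG", maxMissed = 0, offset = 101,
                              seqid = "frag")
  expect_equal(peptideTable(ps2)$start, c(101L, 103L, 106L))
  tsv <- tempfile(fileext = ".tsv")
  writePeptidesTsv(ps2, tsv)
  expect_equal(read.delim(tsv)$end, c(102L, 105L, 106L))
})

test_that("fold coverage counts overlapping peptides and covered positions", {
  empty <- chymotrypticPeptides("AAA", maxMissed = 0, minLength = 5)
  expect_equal(foldCoverage(empty, segmentSpec("seq1", 1, 3)),
               list(nOverlapping = 0L, fractionCovered = 0))

  one <- chymotrypticPeptides("GGGF", maxMissed = 0)   # single peptide 1-4
  expect_equal(foldCoverage(one, segmentSpec("seq1", 1, 4)),
               list(nOverlapping = 1L, fractionCovered = 1.0))

  expect_error(foldCoverage(one, segmentSpec("other", 1, 4)), "fold is on")

  ## per-position tally oracle on a random digest
  set.seed(31)
  seqc <- paste(sample(AA, 80, replace = TRUE), collapse = "")
  ps <- chymotrypticPeptides(seqc, maxMissed = 2)
  fold <- segmentSpec("seq1", 21, 55)
  got <- foldCoverage(ps, fold)
  tab <- peptideTable(ps)
  ov <- tab$end >= 21 & tab$start <= 55
  cov <- vapply(21:55, function(pos)
    any(tab$start <= pos & tab$end >= pos), logical(1))
  expect_equal(got$nOverlapping, sum(ov))
  expect_equal(got$fractionCovered, mean(cov))
})
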