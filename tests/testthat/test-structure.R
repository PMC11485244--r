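test_that("PDB and mmCIF parse to identical atomic models", {
  fix <- toyInterfaceFixture()
  mp <- readStructure(fix$pdb)
  mc <- readStructure(fix$cif)
  ap <- atomTable(mp); ac <- atomTable(mc)
  expect_equal(nrow(ap), nrow(ac))
  expect_equal(ap$chain, ac$chain)
  expect_equal(ap$resno, ac$resno)
  expect_equal(ap$resid, ac$resid)
  expect_equal(ap$elety, ac$elety)
  expect_equal(ap[, c("x", "y", "z")], ac[, c("x", "y", "z")],
               tolerance = 1e-6)
  ## 2 chains x 3 residues; GAS has no CB on G: 4+5+5 atoms, VAL: 5+5+5
  expect_equal(nrow(ap), 29L)
})

test_that("single-residue toy model round-trips and bad files error", {
  pdb <- tempfile(fileext = ".pdb"); cif <- tempfile(fileext = ".cif")
  generateToyStructure(list(A = "A"), pdbPath = pdb, cifPath = cif)
  m <- readStructure(pdb)
  expect_equal(nrow(atomTable(m)), 5L)   # N CA C O CB
  expect_equal(unique(atomTable(m)$resid), "ALA")
  expect_equal(nrow(atomTable(readStructure(cif))), 5L)

  trunc <- tempfile(fileext = ".pdb")
  writeLines(c(readLines(pdb)[1], "ATOM      2  CA"), trunc)
  expect_error(readStructure(trunc), "line 2")
  expect_error(readStructure(tempfile(fileext = ".pdb")), "not found")
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  OG ASER A   1       2.000   1.000   0.000  0.30  0.00           O",
    "ATOM      4  OG BSER A   1       2.000  -1.000   0.000  0.70  0.00           O",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  a <- atomTable(readStructure(path))
  og <- a[a$elety == "OG", ]
  expect_equal(nrow(og), 1L)
  expect_equal(og$y, -1.0)
  expect_equal(og$occupancy, 0.7)
})

test_that("well-separated chains have an empty interface", {
  fix <- toyInterfaceFixture(displacement = c(0, 0, 20))
  rep <- interfaceSideChains(readStructure(fix$pdb), "A:1-3", "B:1-3",
                             cutoff = 4.5)
  s <- interfaceSummary(rep)
  expect_equal(s$nInterfaceSideChains, 0L)
  expect_equal(s$nHydrophobic, 0L)
  expect_true(is.na(s$fractionHydrophobic))
  expect_true(all(!interfaceResidues(rep)$inInterface))
})

test_that("interface flags equal a brute-force all-pairs distance oracle", {
  for (dz in c(3, 4.6, 5.5, 7)) {
    fix <- toyInterfaceFixture(displacement = c(0, 0.7, dz))
    model <- readStructure(fix$pdb)
    for (cutoff in c(4.0, 4.5, 5.0)) {
      rep <- interfaceSideChains(model, "A:1-3", "B:1-3", cutoff = cutoff)
      got <- interfaceResidues(rep)
      want <- oracleInterface(atomTable(model), "A", "B", cutoff)
      key <- paste(want$chain, want$resno)
      expect_equal(got$inInterface,
                   want$inInterface[match(paste(got$chain, got$resno), key)])
      s <- interfaceSummary(rep)
      expect_equal(s$nInterfaceSideChains, sum(got$inInterface))
      if (s$nInterfaceSideChains > 0)
        expect_equal(s$fractionHydrophobic,
                     sum(got$inInterface & got$hydrophobic) /
                       sum(got$inInterface))
    }
  }
})

test_that("glycine is never an interface side chain", {
  fix <- toyInterfaceFixture(displacement = c(0, 0, 2.5))  # very tight contact
  rep <- interfaceSideChains(readStructure(fix$pdb), "A:1-3", "B:1-3", 4.5)
  got <- interfaceResidues(rep)
  expect_false(any(got$resid == "GLY"))
  ## chain A = G A S: only A and S can appear
  expect_setequal(unique(got$resid[got$range == "A"]), c("ALA", "SER"))
})

test_that("the interface report is symmetric and monotone in the cutoff", {
  fix <- toyInterfaceFixture(displacement = c(0.3, 0.5, 4.8))
  model <- readStructure(fix$pdb)
  ab <- interfaceSideChains(model, "A:1-3", "B:1-3", 4.5)
  ba <- interfaceSideChains(model, "B:1-3", "A:1-3", 4.5)
  keyAB <- with(interfaceResidues(ab), paste(chain, resno, inInterface))
  keyBA <- with(interfaceResidues(ba), paste(chain, resno, inInterface))
  expect_setequal(keyAB, keyBA)
  expect_equal(interfaceSummary(ab)$nInterfaceSideChains,
               interfaceSummary(ba)$nInterfaceSideChains)

  sets <- lapply(seq(4.0, 5.0, by = 0.25), function(ct) {
    r <- interfaceResidues(interfaceSideChains(model, "A:1-3", "B:1-3", ct))
    paste(r$chain, r$resno)[r$inInterface]
  })
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))

  expect_error(interfaceSideChains(model, "C:1-3", "B:1-3", 4.5),
               "not present")
  expect_error(interfaceSideChains(model, "A:1-3", "B:1-3", -1), "cutoff")
})

test_that("hydrogen-bond detection follows distance and angle criteria", {
  ## two alanines, CB atoms 2.9 A apart along z (displacement tuned so the
  ## chosen donor/acceptor pair has a known distance)
  pdb <- tempfile(fileext = ".pdb")
  generateToyStructure(list(A = "A", B = "A"), displacement = c(0, 0, 2.9),
                       pdbPath = pdb)
  model <- readStructure(pdb)
  hb <- hbondPresent(model, donor = list(chain = "A", resno = 1, atoms = "CB"),
                     acceptor = list(chain = "B", resno = 1, atoms = "CB"))
  expect_true(hb$present)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_true(is.na(hb$angle))   # no hydrogens in the model

  far <- hbondPresent(model, donor = list(chain = "A", resno = 1, atoms = "N"),
                      acceptor = list(chain = "B", resno = 1, atoms = "O"))
  expect_false(far$present)
  expect_gt(far$distance, 3.5)

  expect_error(
    hbondPresent(model, donor = list(chain = "A", resno = 1, atoms = "NE2"),
                 acceptor = list(chain = "B", resno = 1, atoms = "CB")),
    "donor atom.*NE2")
})

test_that("explicit donor hydrogens enforce the D-H...A angle", {
  mk <- function(hx, hy, hz) {
    lines <- c(
      "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
      sprintf("ATOM      2  H   ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           H",
              hx, hy, hz),
      "ATOM      3  O   ALA B   2       0.000   0.000   2.900  1.00  0.00           O",
      "END")
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    readStructure(path)
  }
  don <- list(chain = "A", resno = 1, atoms = "N")
  acc <- list(chain = "B", resno = 2, atoms = "O")
  ## H on the N-O axis: angle 180 degrees
  lin <- hbondPresent(mk(0, 0, 1.0), don, acc)
  expect_true(lin$present)
  expect_equal(lin$angle, 180, tolerance = 1e-6)
  ## H perpendicular: angle ~66 deg < 120 -> rejected despite the distance
  bent <- hbondPresent(mk(1.0, 0, 0), don, acc)
  expect_false(bent$present)
  expect_lt(bent$angle, 120)
})

test_that("solvent contacts report bridging waters and tolerate dry models", {
  dry <- toyInterfaceFixture()
  expect_equal(nrow(solventContacts(readStructure(dry$pdb))), 0L)

  ## place a water 2.8 A from chain A's Ser OG-side (use CB here) and from
  ## chain B's backbone N: both polar atoms within 3.5 A are reported
  fix <- toyInterfaceFixture(displacement = c(0, 0, 5.6),
                             waters = matrix(c(0, 0, 2.8), nrow = 1))
  model <- readStructure(fix$pdb)
  sc <- solventContacts(model, cutoff = 3.5)
  expect_gt(nrow(sc), 1L)
  expect_setequal(unique(sc$chain), c("A", "B"))
  expect_true(all(sc$distance <= 3.5))
  ## distances match a direct computation
  a <- atomTable(model)
  w <- a[a$resid == "HOH", ]
  for (i in seq_len(nrow(sc))) {
    at <- a[a$chain == sc$chain[i] & a$resno == sc$resno[i] &
              a$elety == sc$atom[i], ]
    expect_equal(sc$distance[i],
                 sqrt(sum((c(at$x, at$y, at$z) - c(w$x, w$y, w$z))^2)),
                 tolerance = 1e-6)
  }
  ## restriction to named residues
  sc2 <- solventContacts(model, cutoff = 3.5,
                         residues = list(list(chain = "A", resno = 1)))
  expect_true(all(sc2$chain == "A" & sc2$resno == 1))
})
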