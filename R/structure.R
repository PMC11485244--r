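## Atomic models and inter-chain interface characterization.

#' Read an atomic model from PDB or mmCIF
#'
#' Parses coordinates with bio3d ([bio3d::read.pdb()] / [bio3d::read.cif()]),
#' preserving author chain identifiers, residue numbers and insertion codes.
#' When alternate conformers are present, only the highest-occupancy
#' conformer of each atom is kept (ties: first in file).
#'
#' @param path model file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return an [AtomicModel-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif"
              else "pdb"
  }
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    atomLines <- grep("^(ATOM|HETATM)", lines)
    short <- atomLines[nchar(lines[atomLines]) < 54L]
    if (length(short))
      stop(sprintf("truncated ATOM/HETATM record at line %d of '%s'",
                   short[[1L]], path))
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                    error = function(e)
                      stop(sprintf("could not parse PDB '%s': %s", path,
                                   conditionMessage(e))))
  } else {
    pdb <- tryCatch(suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)),
                    error = function(e)
                      stop(sprintf("could not parse mmCIF '%s': %s", path,
                                   conditionMessage(e))))
  }
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop(sprintf("empty model in '%s'", path))
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert) | a$insert == "", "", as.character(a$insert)),
    resid = as.character(a$resid), elety = as.character(a$elety),
    elesy = toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                           substr(gsub("[0-9]", "", a$elety), 1L, 1L),
                           as.character(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    type = as.character(a$type),
    stringsAsFactors = FALSE)
  ## altloc policy: highest occupancy conformer per atom
  alt <- if (!is.null(a$alt)) ifelse(is.na(a$alt), "", as.character(a$alt))
         else rep("", nrow(a))
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
    keep <- order(-atoms$occupancy)
    keep <- keep[!duplicated(key[keep])]
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  new("AtomicModel", atoms = atoms, source = path)
}

#' @rdname readStructure
#' @param model an [AtomicModel-class].
#' @export
atomTable <- function(model) {
  stopifnot(is(model, "AtomicModel"))
  model@atoms
}

setMethod("show", "AtomicModel", function(object) {
  a <- object@atoms
  rk <- unique(paste(a$chain, a$resno, a$insert))
  cat(sprintf("AtomicModel from '%s': %d chain(s), %d residue(s), %d atom(s)\n",
              object@source, length(unique(a$chain)), length(rk), nrow(a)))
  invisible(object)
})

#' Parse a chain:range selection
#'
#' `"B:55-74"` means residues 55-74 of chain B.
#'
#' @param x selection string, or a list with elements `chain`, `start`, `end`
#'   (returned unchanged).
#' @return list with `chain`, `start`, `end`.
#' @export
parseRange <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("chain", "start", "end") %in% names(x)))
    return(x[c("chain", "start", "end")])
  }
  m <- regexec("^([A-Za-z0-9]+):(\\d+)-(\\d+)$", x)
  parts <- regmatches(x, m)[[1L]]
  if (length(parts) != 4L)
    stop(sprintf("cannot parse range '%s' (expected CHAIN:START-END)", x))
  list(chain = parts[[2L]], start = as.integer(parts[[3L]]),
       end = as.integer(parts[[4L]]))
}

## Heavy (non-hydrogen) protein atoms of a chain:range selection.
rangeAtoms <- function(model, range) {
  a <- model@atoms
  sel <- a$chain == range$chain & a$resno >= range$start &
    a$resno <= range$end & a$elesy != "H" & a$resid %in% names(AA3TO1)
  if (!any(sel))
    stop(sprintf("range %s:%d-%d not present in the model",
                 range$chain, range$start, range$end))
  a[sel, , drop = FALSE]
}

#' Inter-chain interface side chains and hydrophobic fraction
#'
#' A residue's side chain participates in the interface when at least one of
#' its side-chain heavy atoms (all non-hydrogen atoms beyond the backbone,
#' CB included) lies within `cutoff` of any heavy atom of the other range.
#' Glycine has no side chain and is never counted. The summary reports the
#' number of participating side chains from both ranges and the fraction
#' classified hydrophobic (default set A, V, L, I, M, F, W, C, P; tyrosine
#' counts as polar aromatic).
#'
#' @param model an [AtomicModel-class].
#' @param rangeA,rangeB selections (string `"B:55-74"` or list; see
#'   [parseRange()]).
#' @param cutoff contact distance in Angstrom between heavy atoms
#'   (default 4.5, a common van der Waals contact criterion).
#' @param hydrophobic residue letters classified as hydrophobic.
#' @return an [InterfaceReport-class].
#' @export
interfaceSideChains <- function(model, rangeA, rangeB, cutoff = 4.5,
                                hydrophobic = HYDROPHOBIC_DEFAULT) {
  stopifnot(is(model, "AtomicModel"))
  if (cutoff <= 0) stop("cutoff must be positive")
  rangeA <- parseRange(rangeA)
  rangeB <- parseRange(rangeB)
  atomsA <- rangeAtoms(model, rangeA)
  atomsB <- rangeAtoms(model, rangeB)

  perResidue <- function(self, other, label) {
    sc <- self[!(self$elety %in% BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(sc) == 0L)
      return(data.frame(range = character(0), chain = character(0),
                        resno = integer(0), resid = character(0),
                        minDistance = numeric(0), inInterface = logical(0),
                        hydrophobic = logical(0), stringsAsFactors = FALSE))
    d <- crossDistances(as.matrix(sc[, c("x", "y", "z")]),
                        as.matrix(other[, c("x", "y", "z")]))
    key <- paste(sc$chain, sc$resno, sc$insert, sep = "|")
    mind <- tapply(apply(d, 1L, min), key, min)
    first <- !duplicated(key)
    info <- sc[first, c("chain", "resno", "insert", "resid")]
    ord <- order(info$resno, info$insert)
    info <- info[ord, , drop = FALSE]
    mind <- as.numeric(mind[paste(info$chain, info$resno, info$insert,
                                  sep = "|")])
    one <- AA3TO1[info$resid]
    data.frame(range = label, chain = info$chain, resno = info$resno,
               resid = info$resid, minDistance = mind,
               inInterface = mind <= cutoff,
               hydrophobic = !is.na(one) & one %in% hydrophobic,
               stringsAsFactors = FALSE)
  }

  residues <- rbind(perResidue(atomsA, atomsB, "A"),
                    perResidue(atomsB, atomsA, "B"))
  rownames(residues) <- NULL
  nInt <- sum(residues$inInterface)
  nHyd <- sum(residues$inInterface & residues$hydrophobic)
  new("InterfaceReport", residues = residues,
      summary = list(nInterfaceSideChains = nInt, nHydrophobic = nHyd,
                     fractionHydrophobic = if (nInt > 0) nHyd / nInt else NA_real_,
                     cutoff = cutoff))
}

#' @rdname interfaceSideChains
#' @param report an [InterfaceReport-class].
#' @export
interfaceResidues <- function(report) {
  stopifnot(is(report, "InterfaceReport"))
  report@residues
}

#' @rdname interfaceSideChains
#' @export
interfaceSummary <- function(report) {
  stopifnot(is(report, "InterfaceReport"))
  report@summary
}

setMethod("show", "InterfaceReport", function(object) {
  s <- object@summary
  cat(sprintf(
    "InterfaceReport (cutoff %.2f A): %d side chain(s) in interface, %d hydrophobic (%.0f%%)\n",
    s$cutoff, s$nInterfaceSideChains, s$nHydrophobic,
    100 * s$fractionHydrophobic))
  invisible(object)
})

## Resolve an atom specification to rows of the atom table.
resolveAtoms <- function(model, spec, what) {
  a <- model@atoms
  sel <- a$chain == spec$chain & a$resno == spec$resno &
    a$elety %in% spec$atoms
  if (!any(sel)) {
    stop(sprintf("%s atom(s) not found: chain %s residue %d atom(s) %s",
                 what, spec$chain, spec$resno,
                 paste(spec$atoms, collapse = "/")))
  }
  a[sel, , drop = FALSE]
}

#' Test for a hydrogen bond between two atom groups
#'
#' Geometric criterion: the minimum donor--acceptor heavy-atom distance must
#' not exceed `distanceCutoff`; additionally, when the model contains a
#' hydrogen bonded to the donor atom (within 1.2 Angstrom), the D-H...A
#' angle must be at least `angleCutoff`. Deposited cryo-EM models usually
#' omit hydrogens, in which case the distance criterion alone decides and
#' the returned angle is `NA`.
#'
#' @param model an [AtomicModel-class].
#' @param donor,acceptor lists with `chain`, `resno`, `atoms` (character
#'   vector of candidate atom names, e.g. `c("NE2","OE1")` for a glutamine
#'   side-chain amide).
#' @param distanceCutoff heavy-atom distance cutoff in Angstrom
#'   (default 3.5).
#' @param angleCutoff minimum D-H...A angle in degrees (default 120), used
#'   only when a donor hydrogen is present.
#' @return list with `present`, `distance`, `donorAtom`, `acceptorAtom`,
#'   `angle` (degrees or `NA`).
#' @export
hbondPresent <- function(model, donor, acceptor, distanceCutoff = 3.5,
                         angleCutoff = 120) {
  stopifnot(is(model, "AtomicModel"))
  dAtoms <- resolveAtoms(model, donor, "donor")
  aAtoms <- resolveAtoms(model, acceptor, "acceptor")
  dHeavy <- dAtoms[dAtoms$elesy != "H", , drop = FALSE]
  aHeavy <- aAtoms[aAtoms$elesy != "H", , drop = FALSE]
  if (nrow(dHeavy) == 0L || nrow(aHeavy) == 0L)
    stop("donor/acceptor selections contain no heavy atoms")
  d <- crossDistances(as.matrix(dHeavy[, c("x", "y", "z")]),
                      as.matrix(aHeavy[, c("x", "y", "z")]))
  best <- which(d == min(d), arr.ind = TRUE)[1L, ]
  dist <- min(d)
  don <- dHeavy[best[[1L]], ]
  acc <- aHeavy[best[[2L]], ]
  present <- dist <= distanceCutoff

  ## D-H...A angle when an explicit donor hydrogen exists
  angle <- NA_real_
  all_a <- model@atoms
  hs <- all_a[all_a$elesy == "H" & all_a$chain == don$chain &
                all_a$resno == don$resno, , drop = FALSE]
  if (nrow(hs)) {
    dh <- crossDistances(as.matrix(hs[, c("x", "y", "z")]),
                         matrix(c(don$x, don$y, don$z), ncol = 3L))
    bonded <- which(dh[, 1L] <= 1.2)
    if (length(bonded)) {
      angles <- vapply(bonded, function(k) {
        h <- c(hs$x[[k]], hs$y[[k]], hs$z[[k]])
        v1 <- c(don$x, don$y, don$z) - h
        v2 <- c(acc$x, acc$y, acc$z) - h
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }, numeric(1))
      angle <- max(angles)
      present <- present && angle >= angleCutoff
    }
  }
  list(present = present, distance = dist, donorAtom = don$elety,
       acceptorAtom = acc$elety, angle = angle)
}

#' Solvent-mediated polar contacts
#'
#' For each ordered solvent site in the model (residue names HOH/WAT/...),
#' lists the protein polar atoms (N or O) within `cutoff`. Buried waters
#' bridging two chains of a filament interface show up here as one site
#' contacting residues of both proteins.
#'
#' @param model an [AtomicModel-class].
#' @param cutoff polar contact distance in Angstrom (default 3.5).
#' @param solventNames residue names treated as solvent.
#' @param residues optional list of `list(chain=, resno=)` specs restricting
#'   the reported protein residues.
#' @return data.frame with one row per (solvent site, contacting atom):
#'   `solventChain`, `solventResno`, `chain`, `resno`, `resid`, `atom`,
#'   `distance`. Zero rows when the model has no solvent.
#' @export
solventContacts <- function(model, cutoff = 3.5,
                            solventNames = SOLVENT_RESNAMES, residues = NULL) {
  stopifnot(is(model, "AtomicModel"))
  a <- model@atoms
  solv <- a[a$resid %in% solventNames & a$elesy != "H", , drop = FALSE]
  empty <- data.frame(solventChain = character(0), solventResno = integer(0),
                      chain = character(0), resno = integer(0),
                      resid = character(0), atom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(solv) == 0L) return(empty)
  polar <- a[a$resid %in% names(AA3TO1) & a$elesy %in% c("N", "O"), ,
             drop = FALSE]
  if (!is.null(residues)) {
    keep <- rep(FALSE, nrow(polar))
    for (spec in residues)
      keep <- keep | (polar$chain == spec$chain & polar$resno == spec$resno)
    polar <- polar[keep, , drop = FALSE]
  }
  if (nrow(polar) == 0L) return(empty)
  d <- crossDistances(as.matrix(solv[, c("x", "y", "z")]),
                      as.matrix(polar[, c("x", "y", "z")]))
  idx <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  out <- data.frame(
    solventChain = solv$chain[idx[, 1L]], solventResno = solv$resno[idx[, 1L]],
    chain = polar$chain[idx[, 2L]], resno = polar$resno[idx[, 2L]],
    resid = polar$resid[idx[, 2L]], atom = polar$elety[idx[, 2L]],
    distance = d[idx], stringsAsFactors = FALSE)
  out <- out[order(out$solventChain, out$solventResno, out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}
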