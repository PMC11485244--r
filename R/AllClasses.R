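#' @import methods
NULL

#' Degenerate residue pattern
#'
#' An `AmbiguityPattern` is an ordered list of positions, each of which is a
#' non-empty subset of the 20 standard amino acids. A position whose set is
#' the full alphabet is a wildcard (written `X`). Patterns of this kind arise
#' when reading a protein sequence directly out of cryo-EM side-chain
#' densities: a well-resolved side chain pins one residue, a partially
#' resolved one narrows it to a class (for example `[SA]` or `[WF]`), and an
#' uninterpretable one is a wildcard.
#'
#' @slot positions list of character vectors, each a sorted subset of the
#'   standard amino-acid alphabet.
#'
#' @seealso [parsePattern()], [patternToString()], [matchProbability()]
#' @export
setClass("AmbiguityPattern", representation(positions = "list"))

setValidity("AmbiguityPattern", function(object) {
  pos <- object@positions
  if (length(pos) < 1L)
    return("pattern must have at least one position")
  for (i in seq_along(pos)) {
    s <- pos[[i]]
    if (!is.character(s) || length(s) < 1L)
      return(sprintf("position %d: residue set is empty", i))
    if (anyDuplicated(s))
      return(sprintf("position %d: duplicated residues", i))
    if (!all(s %in% AA20))
      return(sprintf("position %d: letters outside the 20-residue alphabet", i))
    if (is.unsorted(s))
      return(sprintf("position %d: residue set must be stored sorted", i))
  }
  TRUE
})

#' Background amino-acid frequency model
#'
#' Null model for residue occurrence used to score how surprising a pattern
#' match is. The uniform model assigns 0.05 to each residue; an empirical
#' model can be computed from the scanned proteome itself.
#'
#' @slot frequencies named numeric vector over the 20 standard residues,
#'   non-negative, summing to 1.
#'
#' @seealso [uniformBackground()], [empiricalBackground()]
#' @export
setClass("BackgroundModel", representation(frequencies = "numeric"))

setValidity("BackgroundModel", function(object) {
  f <- object@frequencies
  if (length(f) != 20L || !identical(sort(names(f)), sort(AA20)))
    return("frequencies must be named over the 20 standard residues")
  if (any(f < 0))
    return("frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-9)
    return("frequencies must sum to 1 (tolerance 1e-9)")
  TRUE
})

#' Uniqueness statistics for a pattern against a background
#'
#' Summarizes how discriminating a degenerate pattern is: the probability a
#' single random window matches (`pWindow`), the Poisson-expected number of
#' matches among `totalWindows` background windows, the information content
#' in bits, and the probabilities of at least one background hit
#' (`pAnyHit = 1 - exp(-E)`) and of none (`pUnique = exp(-E)`). A scan that
#' returns a single protein is convincing exactly when `pUnique` is close
#' to 1.
#'
#' @slot pWindow probability a random window matches.
#' @slot totalWindows number of windows scanned (sum over sequences of
#'   `max(0, L - m + 1)`).
#' @slot expectedHits expected number of background matches.
#' @slot informationBits pattern information content, `-log2(pWindow)`.
#' @slot pAnyHit probability of one or more background hits.
#' @slot pUnique probability of zero background hits.
#'
#' @seealso [expectedHits()], [matchProbability()], [informationContent()]
#' @export
setClass("MatchStatistics", representation(
  pWindow = "numeric", totalWindows = "numeric", expectedHits = "numeric",
  informationBits = "numeric", pAnyHit = "numeric", pUnique = "numeric"))

setValidity("MatchStatistics", function(object) {
  if (object@pWindow < 0 || object@pWindow > 1)
    return("pWindow must lie in [0, 1]")
  if (object@totalWindows < 0) return("totalWindows must be non-negative")
  if (object@expectedHits < 0) return("expectedHits must be non-negative")
  TRUE
})

#' Resolution-tiered residue confusion model
#'
#' Models which amino acids are indistinguishable by side-chain density at a
#' given local map quality. Each tier is a full partition of the 20-residue
#' alphabet; tier 1 is the best resolved (typically all singletons) and later
#' tiers merge ever larger classes, ending in a single class that derives a
#' wildcard. Tiers must refine: every class at tier t is contained in a class
#' at tier t + 1.
#'
#' @slot tiers list of partitions; each partition is a list of character
#'   vectors jointly covering the alphabet exactly once.
#' @slot tierProbabilities numeric vector, one sampling weight per tier, used
#'   when tiers are drawn at random per position; sums to 1.
#'
#' @seealso [confusionModel()], [defaultConfusionModel()], [derivePattern()]
#' @export
setClass("ConfusionModel", representation(
  tiers = "list", tierProbabilities = "numeric"))

setValidity("ConfusionModel", function(object) {
  tiers <- object@tiers
  if (length(tiers) < 1L) return("at least one tier required")
  for (t in seq_along(tiers)) {
    classes <- tiers[[t]]
    all_res <- sort(unlist(classes))
    if (!identical(all_res, sort(AA20)))
      return(sprintf("tier %d is not a partition of the 20-residue alphabet", t))
  }
  ## refinement: each class of tier t lies inside one class of tier t+1
  for (t in seq_len(length(tiers) - 1L)) {
    for (cl in tiers[[t]]) {
      ok <- vapply(tiers[[t + 1L]], function(cl2) all(cl %in% cl2), logical(1))
      if (!any(ok))
        return(sprintf(
          "tier %d class {%s} is not contained in any tier %d class",
          t, paste(cl, collapse = ","), t + 1L))
    }
  }
  p <- object@tierProbabilities
  if (length(p) != length(tiers))
    return("tierProbabilities must have one entry per tier")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    return("tierProbabilities must be non-negative and sum to 1")
  TRUE
})

#' Identification-recovery simulation result
#'
#' @slot fractionUnique proportion of replicates in which the embedded true
#'   protein was the only protein with a hit.
#' @slot fractionContainsTrue proportion in which it was among the hits.
#' @slot replicates number of replicates run.
#' @slot seed base seed; replicate r uses `seed + r`.
#' @slot parameters list of simulation parameters (m, decoys, length, ...).
#' @slot perReplicate logical matrix, one row per replicate, columns
#'   `unique` and `containsTrue`.
#'
#' @seealso [simulateRecovery()]
#' @export
setClass("RecoveryResult", representation(
  fractionUnique = "numeric", fractionContainsTrue = "numeric",
  replicates = "integer", seed = "integer", parameters = "list",
  perReplicate = "matrix"))

setValidity("RecoveryResult", function(object) {
  fu <- object@fractionUnique; fc <- object@fractionContainsTrue
  if (fu < 0 || fc > 1 || fu > fc)
    return("need 0 <= fractionUnique <= fractionContainsTrue <= 1")
  TRUE
})

#' Residue range on a named parent sequence
#'
#' A 1-based inclusive span in the parent's full-length residue numbering
#' (UniProt-style), e.g. ANXA11 39-74 or TDP-43 282-345.
#'
#' @slot seqid parent sequence identifier.
#' @slot start,end 1-based inclusive residue indices, `start <= end`.
#'
#' @seealso [segmentSpec()], [segmentMass()], [foldCoverage()]
#' @export
setClass("SegmentSpec", representation(
  seqid = "character", start = "integer", end = "integer"))

setValidity("SegmentSpec", function(object) {
  if (length(object@seqid) != 1L || is.na(object@seqid) || !nzchar(object@seqid))
    return("seqid must be a single non-empty string")
  if (object@start < 1L) return("start must be >= 1")
  if (object@end < object@start) return("end must be >= start")
  TRUE
})

#' In-silico digestion product set
#'
#' Peptides produced by a site-specific protease, each with its span in
#' parent numbering, sequence, missed-cleavage count and mass.
#'
#' @slot peptides data.frame with columns `start`, `end`, `sequence`,
#'   `missed`, `mass`.
#' @slot seqid parent sequence identifier.
#' @slot parameters digestion parameters (enzyme residues, max missed
#'   cleavages, proline rule, length window, mass mode).
#'
#' @seealso [chymotrypticPeptides()], [foldCoverage()]
#' @export
setClass("PeptideSet", representation(
  peptides = "data.frame", seqid = "character", parameters = "list"))

setValidity("PeptideSet", function(object) {
  need <- c("start", "end", "sequence", "missed", "mass")
  if (!all(need %in% names(object@peptides)))
    return("peptides must have columns start, end, sequence, missed, mass")
  maxm <- object@parameters$maxMissed
  if (!is.null(maxm) && nrow(object@peptides) &&
      any(object@peptides$missed > maxm))
    return("peptide with more missed cleavages than the configured maximum")
  TRUE
})

#' Helical symmetry of a filament
#'
#' Twist (degrees per rung, signed: negative = left-handed) and rise
#' (Angstrom per rung) relating successive rungs of an amyloid filament.
#'
#' @slot twist degrees per rung, `0 < |twist| <= 180`.
#' @slot rise Angstrom per rung, `> 0`.
#'
#' @seealso [helicalSymmetry()], [crossoverFromSymmetry()]
#' @export
setClass("HelicalSymmetry", representation(twist = "numeric", rise = "numeric"))

setValidity("HelicalSymmetry", function(object) {
  if (!is.finite(object@twist) || object@twist == 0 || abs(object@twist) > 180)
    return("|twist| must lie in (0, 180] degrees")
  if (!is.finite(object@rise) || object@rise <= 0)
    return("rise must be positive")
  TRUE
})

#' Atomic model from a PDB or mmCIF file
#'
#' Flat atom table with author residue numbering preserved. Only the
#' highest-occupancy alternate conformer of each atom is kept.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (atom name), `elesy` (element), `x`, `y`, `z`, `occupancy`,
#'   `type` (ATOM/HETATM).
#' @slot source path the model was read from.
#'
#' @seealso [readStructure()], [interfaceSideChains()]
#' @export
setClass("AtomicModel", representation(atoms = "data.frame", source = "character"))

setValidity("AtomicModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "occupancy", "type")
  if (!all(need %in% names(a)))
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("empty model")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  TRUE
})

#' Inter-chain interface report
#'
#' Per-residue contact flags and a hydrophobicity summary for the interface
#' between two residue ranges of an atomic model. A residue participates in
#' the interface when at least one of its side-chain heavy atoms lies within
#' the cutoff of any heavy atom of the other range; glycine, having no side
#' chain, is never counted.
#'
#' @slot residues data.frame: one row per side-chain-bearing residue of the
#'   two ranges, with columns `range` ("A"/"B"), `chain`, `resno`, `resid`,
#'   `minDistance`, `inInterface`, `hydrophobic`.
#' @slot summary list with `nInterfaceSideChains`, `nHydrophobic`,
#'   `fractionHydrophobic`, `cutoff`.
#'
#' @seealso [interfaceSideChains()]
#' @export
setClass("InterfaceReport", representation(residues = "data.frame", summary = "list"))

setValidity("InterfaceReport", function(object) {
  s <- object@summary
  if (!all(c("nInterfaceSideChains", "nHydrophobic", "fractionHydrophobic") %in%
           names(s)))
    return("summary must contain interface counts and hydrophobic fraction")
  if (s$nInterfaceSideChains > 0 &&
      abs(s$fractionHydrophobic - s$nHydrophobic / s$nInterfaceSideChains) > 1e-12)
    return("fractionHydrophobic inconsistent with counts")
  TRUE
})
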