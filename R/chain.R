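## Sequence-level arithmetic on named chains: segment masses, composition,
## fragment-boundary estimation from apparent mass, in-silico chymotryptic
## digestion and fold-region peptide coverage.

#' Residue mass table
#'
#' @param mode `"average"` (default; matches gel/immunoblot kDa estimates)
#'   or `"monoisotopic"`.
#' @return named numeric vector of residue (chain) masses in Da; add one
#'   water ([waterMass()]) for a free peptide.
#' @export
residueMassTable <- function(mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (mode == "average") RESIDUE_MASS_AVERAGE else RESIDUE_MASS_MONO
}

#' @rdname residueMassTable
#' @export
waterMass <- function(mode = c("average", "monoisotopic")) {
  unname(WATER_MASS[[match.arg(mode)]])
}

#' Residue range constructor
#'
#' @param seqid parent sequence identifier (full-length UniProt-style
#'   numbering is assumed throughout).
#' @param start,end 1-based inclusive residue indices.
#' @return a [SegmentSpec-class].
#' @examples
#' segmentSpec("ANXA11", 39, 74)
#' @export
segmentSpec <- function(seqid, start, end) {
  new("SegmentSpec", seqid = as.character(seqid),
      start = as.integer(start), end = as.integer(end))
}

setMethod("show", "SegmentSpec", function(object) {
  cat(sprintf("SegmentSpec %s:%d-%d (%d residues)\n", object@seqid,
              object@start, object@end, object@end - object@start + 1L))
  invisible(object)
})

## Extract the residue letters of a segment from a (possibly partial)
## parent sequence. `offset` is the parent residue number of the first
## letter of `sequence`, so stored fragments keep full-length numbering.
segmentResidues <- function(seg, sequence, offset = 1L) {
  stopifnot(is(seg, "SegmentSpec"))
  s <- asResidueStrings(sequence)
  if (length(s) != 1L) stop("expected a single parent sequence")
  if (!is.null(names(s)) && nzchar(names(s)) && names(s) != seg@seqid)
    stop(sprintf("segment parent '%s' does not match sequence '%s'",
                 seg@seqid, names(s)))
  offset <- as.integer(offset)
  lo <- seg@start - offset + 1L
  hi <- seg@end - offset + 1L
  if (lo < 1L || hi > nchar(s))
    stop(sprintf(
      "segment %d-%d outside the provided sequence (residues %d-%d)",
      seg@start, seg@end, offset, offset + nchar(s) - 1L))
  substring(unname(s), lo, hi)
}

#' Mass of a residue segment
#'
#' Sum of residue masses plus one water, i.e. the mass of the excised
#' peptide. The fold regions of a heteromeric filament can be compared this
#' way with apparent fragment masses from immunoblots.
#'
#' @param seg a [SegmentSpec-class].
#' @param sequence parent sequence (full-length or a fragment; see `offset`).
#' @param mode `"average"` or `"monoisotopic"`.
#' @param offset parent residue number of the first letter of `sequence`
#'   (default 1, i.e. full-length input).
#' @param camCys add carbamidomethyl to every cysteine (fixed modification
#'   used in MS searches). Default `FALSE`.
#' @return mass in Da.
#' @export
segmentMass <- function(seg, sequence, mode = c("average", "monoisotopic"),
                        offset = 1L, camCys = FALSE) {
  mode <- match.arg(mode)
  res <- strsplit(segmentResidues(seg, sequence, offset), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), AA20)
  if (length(bad))
    stop(sprintf("non-standard residue(s) in segment: %s",
                 paste(bad, collapse = ", ")))
  tab <- residueMassTable(mode)
  mass <- sum(tab[res]) + waterMass(mode)
  if (camCys) mass <- mass + sum(res == "C") * unname(CAM_MASS[[mode]])
  mass
}

#' Count a residue within a segment
#'
#' @inheritParams segmentMass
#' @param residue single uppercase residue letter.
#' @return exact count in the inclusive span.
#' @export
countResidue <- function(seg, sequence, residue, offset = 1L) {
  if (!is.character(residue) || length(residue) != 1L || !(residue %in% AA20))
    stop("residue must be a single standard amino-acid letter")
  res <- strsplit(segmentResidues(seg, sequence, offset), "", fixed = TRUE)[[1L]]
  sum(res == residue)
}

#' Estimate a fragment boundary from an apparent mass
#'
#' For an N-terminal fragment of known apparent mass (e.g. a ~22 kDa band on
#' an immunoblot), finds the residue index r such that the mass of residues
#' 1..r is closest to the target; ties break toward the smaller index.
#' For `terminus = "C"`, the fragment is residues r..L and the returned index
#' is r. The result is an estimate of where truncation occurred, not a
#' claim about the actual cleavage site.
#'
#' @param sequence full-length parent sequence.
#' @param targetMass apparent fragment mass in Da.
#' @param terminus `"N"` (default) or `"C"`.
#' @param mode `"average"` or `"monoisotopic"`.
#' @return list with `index` (1-based residue index), `mass` (the fragment
#'   mass at that boundary) and `residual` (mass - target).
#' @export
fragmentBoundaryFromMass <- function(sequence, targetMass,
                                     terminus = c("N", "C"),
                                     mode = c("average", "monoisotopic")) {
  terminus <- match.arg(terminus)
  mode <- match.arg(mode)
  s <- asResidueString(sequence)
  res <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), AA20)
  if (length(bad))
    stop(sprintf("non-standard residue(s): %s", paste(bad, collapse = ", ")))
  tab <- residueMassTable(mode)
  w <- waterMass(mode)
  masses <- if (terminus == "N") cumsum(tab[res]) + w
            else rev(cumsum(rev(tab[res]))) + w
  if (targetMass < min(masses) - w / 2 || targetMass > max(masses) + w / 2)
    stop(sprintf(
      "target mass %.1f Da outside the achievable range [%.1f, %.1f]",
      targetMass, min(masses), max(masses)))
  dev <- abs(masses - targetMass)
  idx <- which(dev == min(dev))[[1L]]   # tie toward smaller index
  list(index = idx, mass = unname(masses[[idx]]),
       residual = unname(masses[[idx]] - targetMass))
}

#' In-silico chymotryptic digestion
#'
#' Cleaves C-terminal to the enzyme's specificity residues (default
#' F, W, Y, L, M), suppressing cleavage when the following residue is
#' proline (`noP = TRUE`, the usual chymotrypsin rule). Returns every
#' peptide spanning at most `maxMissed` internal cleavage sites, the regime
#' used by MS database searches that allow missed cleavages.
#'
#' @param sequence parent sequence (character/AAString; a fragment with
#'   `offset` works too).
#' @param maxMissed maximum internal (missed) cleavage sites per peptide.
#' @param enzymeResidues residues after which the protease cuts.
#' @param noP suppress a cleavage site when the next residue is proline.
#' @param minLength,maxLength peptide length window (residues) to report.
#' @param offset parent residue number of the first letter of `sequence`.
#' @param seqid parent identifier recorded in the result (defaults to the
#'   sequence's name or `"seq1"`).
#' @param mode mass mode for the reported peptide masses.
#' @param camCys apply carbamidomethyl-Cys as a fixed modification to
#'   reported masses.
#' @return a [PeptideSet-class]; peptide spans use parent numbering.
#' @examples
#' peptideTable(chymotrypticPeptides("AFGAWG", maxMissed = 1))
#' @export
chymotrypticPeptides <- function(sequence, maxMissed = 3L,
                                 enzymeResidues = c("F", "W", "Y", "L", "M"),
                                 noP = TRUE, minLength = 1L, maxLength = Inf,
                                 offset = 1L, seqid = NULL,
                                 mode = c("average", "monoisotopic"),
                                 camCys = FALSE) {
  mode <- match.arg(mode)
  if (maxMissed < 0L) stop("maxMissed must be >= 0")
  s <- asResidueStrings(sequence)
  if (length(s) != 1L) stop("expected a single sequence")
  if (is.null(seqid)) seqid <- names(s)
  seqStr <- unname(s)
  res <- strsplit(seqStr, "", fixed = TRUE)[[1L]]
  L <- length(res)
  offset <- as.integer(offset)

  ## cleavage sites: cut after position i (local), optionally not before P
  cut_after <- which(res %in% enzymeResidues)
  cut_after <- cut_after[cut_after < L]
  if (noP) cut_after <- cut_after[res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, L)           # fragment boundaries
  nfrag <- length(bounds) - 1L

  pep <- list()
  tab <- residueMassTable(mode)
  w <- waterMass(mode)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + maxMissed)) {
      lo <- bounds[[i]] + 1L
      hi <- bounds[[j + 1L]]
      len <- hi - lo + 1L
      if (len < minLength || len > maxLength) next
      pseq <- substring(seqStr, lo, hi)
      pres <- res[lo:hi]
      mass <- if (all(pres %in% AA20)) {
        mm <- sum(tab[pres]) + w
        if (camCys) mm <- mm + sum(pres == "C") * unname(CAM_MASS[[mode]])
        mm
      } else NA_real_
      pep[[length(pep) + 1L]] <- data.frame(
        start = lo + offset - 1L, end = hi + offset - 1L, sequence = pseq,
        missed = j - i, mass = mass, stringsAsFactors = FALSE)
    }
  }
  peptides <- if (length(pep)) do.call(rbind, pep)
              else data.frame(start = integer(0), end = integer(0),
                              sequence = character(0), missed = integer(0),
                              mass = numeric(0), stringsAsFactors = FALSE)
  peptides <- peptides[order(peptides$start, peptides$end), , drop = FALSE]
  rownames(peptides) <- NULL
  new("PeptideSet", peptides = peptides,
      seqid = if (is.null(seqid)) "seq1" else seqid,
      parameters = list(enzymeResidues = enzymeResidues,
                        maxMissed = as.integer(maxMissed), noP = noP,
                        minLength = minLength, maxLength = maxLength,
                        mode = mode, camCys = camCys))
}

#' @rdname chymotrypticPeptides
#' @param ps a [PeptideSet-class].
#' @export
peptideTable <- function(ps) {
  stopifnot(is(ps, "PeptideSet"))
  ps@peptides
}

#' @rdname chymotrypticPeptides
#' @export
writePeptidesTsv <- function(ps, path) {
  utils::write.table(peptideTable(ps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "PeptideSet", function(object) {
  cat(sprintf(
    "PeptideSet on %s: %d peptide(s), <=%d missed cleavage(s), enzyme {%s}%s\n",
    object@seqid, nrow(object@peptides), object@parameters$maxMissed,
    paste(object@parameters$enzymeResidues, collapse = ","),
    if (isTRUE(object@parameters$noP)) ", no cut before P" else ""))
  invisible(object)
})

#' Peptide coverage of a fold region
#'
#' How well a digestion product set covers the span of an ordered filament
#' fold: the number of peptides overlapping the fold by at least one residue,
#' and the fraction of fold positions covered by at least one peptide.
#'
#' @param ps a [PeptideSet-class].
#' @param fold a [SegmentSpec-class] on the same parent sequence.
#' @return list with `nOverlapping` and `fractionCovered`.
#' @export
foldCoverage <- function(ps, fold) {
  stopifnot(is(ps, "PeptideSet"), is(fold, "SegmentSpec"))
  if (!identical(ps@seqid, fold@seqid))
    stop(sprintf("peptides are on '%s' but the fold is on '%s'",
                 ps@seqid, fold@seqid))
  p <- ps@peptides
  if (nrow(p) == 0L) return(list(nOverlapping = 0L, fractionCovered = 0))
  ov <- p$end >= fold@start & p$start <= fold@end
  covered <- rep(FALSE, fold@end - fold@start + 1L)
  for (k in which(ov)) {
    lo <- max(p$start[[k]], fold@start) - fold@start + 1L
    hi <- min(p$end[[k]], fold@end) - fold@start + 1L
    covered[lo:hi] <- TRUE
  }
  list(nOverlapping = sum(ov), fractionCovered = mean(covered))
}
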