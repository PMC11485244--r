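## FASTA reading and pattern scanning with residue bitmasks.

#' Read a proteome from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()] with the validation and
#' sanitization policy used throughout the package: record identifiers (the
#' first whitespace-delimited token of each header) must be unique and every
#' record must have a non-empty sequence after sanitization. `*` (stop) and
#' gap characters (`-`, `.`) are stripped with a warning that counts them.
#' Other non-standard letters (B, Z, J, U, O, X) are retained: they never
#' satisfy a non-wildcard pattern position but do satisfy a wildcard.
#'
#' @param path FASTA file (multi-record, wrapped lines supported).
#' @return an `AAStringSet` named by record identifier, with the full header
#'   line kept in `names`' original order; descriptions are in
#'   `attr(x, "descriptions")`.
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- tryCatch(
    Biostrings::readAAStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("could not parse FASTA '%s': %s",
                                     path, conditionMessage(e))))
  if (length(raw) == 0L) stop(sprintf("no FASTA records in '%s'", path))
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record identifiers: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(raw))
  nbefore <- nchar(seqs)
  seqs <- gsub("[*.\\-]", "", seqs)
  stripped <- sum(nbefore - nchar(seqs))
  if (stripped > 0)
    warning(sprintf("stripped %d stop/gap character(s) from '%s'",
                    stripped, path))
  if (any(nchar(seqs) == 0L))
    stop(sprintf("record(s) with no sequence: %s",
                 paste(ids[nchar(seqs) == 0L], collapse = ", ")))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  attr(out, "descriptions") <- stats::setNames(desc, ids)
  out
}

## --- residue bitmask machinery -------------------------------------------
## Bits 1..20: the standard residues in AA20 order. Bit 21: "non-standard
## subject letter" (B, Z, J, U, O, X, ...). A non-wildcard pattern position
## carries bits only for its residues, so a non-standard subject letter can
## never satisfy it; a wildcard position carries all 21 bits.

WILDCARD_MASK <- 2^21 - 1
NONSTANDARD_BIT <- 2^20

residueMaskLUT <- local({
  lut <- rep(NONSTANDARD_BIT, 127L)
  lut[utf8ToInt(paste(AA20, collapse = ""))] <- 2^(seq_len(20L) - 1L)
  lut
})

## Integer masks for each pattern position.
patternMasks <- function(p, ilEquivalent = FALSE) {
  iBit <- 2^(match("I", AA20) - 1L)
  lBit <- 2^(match("L", AA20) - 1L)
  vapply(p@positions, function(s) {
    if (length(s) == 20L) return(WILDCARD_MASK)
    m <- sum(2^(match(s, AA20) - 1L))
    if (ilEquivalent && (bitwAnd(m, iBit) != 0 || bitwAnd(m, lBit) != 0))
      m <- bitwOr(bitwOr(m, iBit), lBit)
    m
  }, numeric(1))
}

## Scan one residue string; returns integer vector of 1-based start indices.
scanOneSequence <- function(seqString, masks) {
  m <- length(masks)
  L <- nchar(seqString)
  if (L < m) return(integer(0))
  codes <- utf8ToInt(seqString)
  codes[codes > 127L | codes < 1L] <- utf8ToInt("X")
  rmask <- residueMaskLUT[codes]
  starts <- seq_len(L - m + 1L)
  for (i in seq_len(m)) {
    if (masks[[i]] == WILDCARD_MASK) next
    starts <- starts[bitwAnd(rmask[starts + i - 1L], masks[[i]]) != 0]
    if (length(starts) == 0L) break
  }
  starts
}

#' Scan a degenerate pattern over a proteome
#'
#' Tests every window of every sequence; overlapping matches are all
#' reported. Matching uses per-position 20-bit residue masks. Coordinates
#' are 1-based inclusive.
#'
#' @param p an [AmbiguityPattern-class].
#' @param proteome an `AAStringSet` (e.g. from [readProteome()]) or named
#'   character vector.
#' @param reverse reverse the position order of the pattern before scanning;
#'   useful when the chain direction read from density is uncertain.
#' @param ilEquivalent treat I and L as interchangeable at every non-wildcard
#'   position that contains either (side-chain density cannot distinguish
#'   them). Off by default.
#' @return data.frame of hits with columns `id`, `start`, `end`, `match`,
#'   sorted by record order then start position.
#' @examples
#' scanProteome(parsePattern("AAA"), c(s1 = "AAAA"))  # starts 1 and 2
#' @export
scanProteome <- function(p, proteome, reverse = FALSE, ilEquivalent = FALSE) {
  stopifnot(is(p, "AmbiguityPattern"))
  seqs <- asResidueStrings(proteome)
  masks <- patternMasks(p, ilEquivalent = ilEquivalent)
  if (reverse) masks <- rev(masks)
  m <- length(masks)
  hits <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    starts <- scanOneSequence(seqs[[k]], masks)
    if (length(starts))
      hits[[k]] <- data.frame(
        id = names(seqs)[[k]], start = starts, end = starts + m - 1L,
        match = substring(seqs[[k]], starts, starts + m - 1L),
        stringsAsFactors = FALSE)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L)
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Number of distinct proteins with at least one hit
#'
#' The headline quantity of a density-derived motif search: identification is
#' unambiguous when exactly one protein in the proteome carries a match.
#'
#' @param hits data.frame from [scanProteome()].
#' @return non-negative integer.
#' @export
countDistinctProteins <- function(hits) {
  stopifnot(is.data.frame(hits), "id" %in% names(hits))
  length(unique(hits$id))
}

#' Write scan results to TSV and a JSON summary
#'
#' @param hits data.frame from [scanProteome()].
#' @param stats optional [MatchStatistics-class] to embed in the summary.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @return invisibly, the summary list.
#' @export
writeScanResults <- function(hits, stats = NULL, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(hits, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(total_hits = nrow(hits),
                  distinct_proteins = countDistinctProteins(hits))
  if (!is.null(stats)) {
    st <- statisticsTable(stats)
    summary$statistics <- stats::setNames(as.list(st$value), st$statistic)
  }
  if (!is.null(json))
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
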