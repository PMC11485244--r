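## Degenerate pattern parsing, serialization and uniqueness statistics.

newPattern <- function(positions) {
  positions <- lapply(positions, function(s) sort(unique(s)))
  new("AmbiguityPattern", positions = positions)
}

#' Parse a bracket-syntax degenerate pattern
#'
#' Grammar: an uppercase residue letter is a fixed position; `[...]` encloses
#' a class of two or more distinct residue letters; `X` is a wildcard
#' matching any residue. This is the syntax in which density-derived motifs
#' are written, e.g. the 11-position motif
#' `"G[NMQ]X[SA][EDRKQN]M[SA][SAG]X[WF][SAG]"` read off well-resolved
#' side-chain densities of a filament chain.
#'
#' @param text pattern string.
#' @return An [AmbiguityPattern-class] object.
#' @examples
#' p <- parsePattern("G[NMQ]X[SA][EDRKQN]M[SA][SAG]X[WF][SAG]")
#' patternLength(p)      # 11
#' patternClassSizes(p)  # 1 3 20 2 6 1 2 3 20 2 3
#' @export
parsePattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("pattern text must be a single non-empty string")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  positions <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "X") {
      positions[[length(positions) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (length(close) == 0L)
        stop(sprintf("unclosed residue class starting at index %d", i))
      close <- close[[1L]]
      members <- chars[seq.int(i + 1L, length.out = close - i - 1L)]
      if (length(members) == 0L)
        stop(sprintf("empty residue class at index %d", i))
      bad <- which(!(members %in% AA20))
      if (length(bad))
        stop(sprintf("invalid character '%s' in residue class at index %d",
                     members[[bad[[1L]]]], i + bad[[1L]]))
      members <- unique(members)
      if (length(members) < 2L)
        stop(sprintf(
          "residue class at index %d has fewer than 2 distinct residues", i))
      positions[[length(positions) + 1L]] <- members
      i <- close + 1L
    } else if (ch %in% letters) {
      stop(sprintf(
        "lowercase character '%s' at index %d (patterns are case-sensitive; use uppercase, wildcard is 'X')",
        ch, i))
    } else {
      stop(sprintf("invalid character '%s' at index %d", ch, i))
    }
  }
  newPattern(positions)
}

#' Serialize a pattern back to bracket syntax
#'
#' Full-alphabet positions are written `X`; singletons as a bare letter;
#' classes in sorted order inside brackets. `parsePattern(patternToString(p))`
#' reproduces `p` exactly.
#'
#' @param p an [AmbiguityPattern-class].
#' @return pattern string.
#' @export
patternToString <- function(p) {
  stopifnot(is(p, "AmbiguityPattern"))
  paste(vapply(p@positions, function(s) {
    if (length(s) == 20L) "X"
    else if (length(s) == 1L) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Convert a PROSITE-style pattern to bracket syntax
#'
#' Accepts dash-separated PROSITE elements: residue letters, `[...]`
#' classes, `x` or `X` wildcards, and `x(n)` repeats. Returns the equivalent
#' bracket-syntax string (no dashes, uppercase `X` wildcards).
#'
#' @param text PROSITE pattern, e.g. `"G-[NMQ]-x-[SA]-x(2)"`. A trailing
#'   period is tolerated.
#' @return bracket-syntax pattern string.
#' @export
prositeToBracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  text <- sub("\\.$", "", trimws(text))
  elements <- strsplit(text, "-", fixed = TRUE)[[1L]]
  out <- character(0)
  for (el in elements) {
    el <- trimws(el)
    rep_m <- regmatches(el, regexec("^([Xx]|\\[[A-Z]+\\]|[A-Z])\\((\\d+)\\)$", el))[[1L]]
    times <- 1L
    if (length(rep_m)) {
      times <- as.integer(rep_m[[3L]])
      el <- rep_m[[2L]]
    }
    if (el %in% c("x", "X")) el <- "X"
    else if (!grepl("^(\\[[A-Z]+\\]|[A-Z])$", el))
      stop(sprintf("unsupported PROSITE element '%s'", el))
    out <- c(out, rep(el, times))
  }
  paste(out, collapse = "")
}

#' @describeIn parsePattern number of positions in a pattern.
#' @export
patternLength <- function(p) {
  stopifnot(is(p, "AmbiguityPattern"))
  length(p@positions)
}

#' @describeIn parsePattern integer vector of class sizes (20 = wildcard).
#' @export
patternClassSizes <- function(p) {
  stopifnot(is(p, "AmbiguityPattern"))
  vapply(p@positions, length, integer(1))
}

#' @describeIn parsePattern list of residue sets, one per position.
#' @export
patternClasses <- function(p) {
  stopifnot(is(p, "AmbiguityPattern"))
  p@positions
}

setMethod("show", "AmbiguityPattern", function(object) {
  cat(sprintf("AmbiguityPattern of length %d: %s\n",
              patternLength(object), patternToString(object)))
  invisible(object)
})

#' Background models
#'
#' `uniformBackground()` assigns each residue probability 0.05.
#' `empiricalBackground()` estimates frequencies from the standard-residue
#' composition of a proteome (an `AAStringSet` or character vector);
#' non-standard letters are ignored.
#'
#' @param proteome sequences to estimate from.
#' @param pseudocount added to each residue count before normalizing, so that
#'   no standard residue has probability exactly zero. Default 1.
#' @return A [BackgroundModel-class].
#' @export
uniformBackground <- function() {
  f <- rep(0.05, 20L)
  names(f) <- AA20
  new("BackgroundModel", frequencies = f)
}

#' @rdname uniformBackground
#' @export
empiricalBackground <- function(proteome, pseudocount = 1) {
  seqs <- asResidueStrings(proteome)
  counts <- integer(20L)
  names(counts) <- AA20
  for (s in seqs) {
    tab <- table(strsplit(s, "", fixed = TRUE)[[1L]])
    keep <- intersect(names(tab), AA20)
    counts[keep] <- counts[keep] + as.integer(tab[keep])
  }
  f <- (counts + pseudocount) / sum(counts + pseudocount)
  new("BackgroundModel", frequencies = f)
}

#' @rdname uniformBackground
#' @param bg a [BackgroundModel-class].
#' @export
bgFrequencies <- function(bg) {
  stopifnot(is(bg, "BackgroundModel"))
  bg@frequencies
}

setMethod("show", "BackgroundModel", function(object) {
  f <- object@frequencies
  cat("BackgroundModel over 20 residues")
  if (max(abs(f - 0.05)) < 1e-12) cat(" (uniform)\n")
  else cat(sprintf(" (min %.4f at %s, max %.4f at %s)\n",
                   min(f), names(which.min(f)), max(f), names(which.max(f))))
  invisible(object)
})

## Per-position match probabilities under a background.
positionProbabilities <- function(p, bg) {
  f <- bgFrequencies(bg)
  vapply(p@positions, function(s) sum(f[s]), numeric(1))
}

#' Probability that a random window matches a pattern
#'
#' Under an i.i.d. background, the probability that a random window of the
#' pattern's length satisfies every position is the product over positions of
#' the background mass of each residue class. Under the uniform background
#' this is `prod(classSize / 20)`.
#'
#' @param p an [AmbiguityPattern-class].
#' @param bg a [BackgroundModel-class]; default uniform.
#' @return probability in `[0, 1]`.
#' @examples
#' matchProbability(parsePattern("A"))   # 0.05
#' matchProbability(parsePattern("XX"))  # 1
#' @export
matchProbability <- function(p, bg = uniformBackground()) {
  stopifnot(is(p, "AmbiguityPattern"), is(bg, "BackgroundModel"))
  prod(positionProbabilities(p, bg))
}

#' Pattern information content in bits
#'
#' `sum_i -log2(P(position i matches))`; additive over positions, zero for an
#' all-wildcard pattern under the uniform background, and equal to
#' `-log2(matchProbability(p, bg))` by construction.
#'
#' @inheritParams matchProbability
#' @return non-negative bits (under any background with no position of
#'   zero probability).
#' @export
informationContent <- function(p, bg = uniformBackground()) {
  stopifnot(is(p, "AmbiguityPattern"), is(bg, "BackgroundModel"))
  pp <- positionProbabilities(p, bg)
  if (any(pp == 0)) {
    bad <- which(pp == 0)[[1L]]
    stop(sprintf(
      "position %d has zero probability under the background (class outside its support)",
      bad))
  }
  sum(-log2(pp))
}

#' Expected background hits and uniqueness probabilities
#'
#' Given the number of scannable windows in a proteome, computes the expected
#' number of chance matches `E = pWindow * totalWindows` and, under a Poisson
#' approximation, the probability of at least one chance hit
#' `1 - exp(-E)` and of none `exp(-E)`. When a proteome search for a
#' density-derived motif returns a single protein, `pUnique` quantifies how
#' unlikely that hit is to be coincidental.
#'
#' @inheritParams matchProbability
#' @param totalWindows non-negative number of windows, i.e. the sum over
#'   sequences of `max(0, L - m + 1)`; see [totalWindowCount()].
#' @return A [MatchStatistics-class].
#' @examples
#' p <- parsePattern("G[NMQ]X[SA][EDRKQN]M[SA][SAG]X[WF][SAG]")
#' expectedHits(p, totalWindows = 1.1e7)
#' @export
expectedHits <- function(p, totalWindows, bg = uniformBackground()) {
  stopifnot(is(p, "AmbiguityPattern"), is(bg, "BackgroundModel"))
  if (!is.numeric(totalWindows) || length(totalWindows) != 1L ||
      is.na(totalWindows) || totalWindows < 0)
    stop("totalWindows must be a single non-negative number")
  pw <- matchProbability(p, bg)
  E <- pw * totalWindows
  new("MatchStatistics",
      pWindow = pw, totalWindows = as.numeric(totalWindows), expectedHits = E,
      informationBits = informationContent(p, bg),
      pAnyHit = -expm1(-E), pUnique = exp(-E))
}

#' Number of scannable windows in a proteome
#'
#' @param proteome an `AAStringSet` or character vector of sequences.
#' @param m pattern length.
#' @return `sum(max(0, nchar - m + 1))` over sequences.
#' @export
totalWindowCount <- function(proteome, m) {
  lens <- if (is(proteome, "XStringSet")) Biostrings::width(proteome)
          else nchar(asResidueStrings(proteome))
  sum(pmax(0, lens - m + 1))
}

#' @rdname expectedHits
#' @param stats a [MatchStatistics-class].
#' @export
pWindow <- function(stats) { stopifnot(is(stats, "MatchStatistics")); stats@pWindow }

#' @rdname expectedHits
#' @export
nExpectedHits <- function(stats) { stopifnot(is(stats, "MatchStatistics")); stats@expectedHits }

#' @rdname expectedHits
#' @export
pAnyHit <- function(stats) { stopifnot(is(stats, "MatchStatistics")); stats@pAnyHit }

#' @rdname expectedHits
#' @export
pUnique <- function(stats) { stopifnot(is(stats, "MatchStatistics")); stats@pUnique }

#' @rdname expectedHits
#' @export
informationBits <- function(stats) { stopifnot(is(stats, "MatchStatistics")); stats@informationBits }

#' @rdname expectedHits
#' @export
statisticsTable <- function(stats) {
  stopifnot(is(stats, "MatchStatistics"))
  data.frame(
    statistic = c("p_window", "total_windows", "expected_hits",
                  "information_bits", "p_any_hit", "p_unique"),
    value = c(stats@pWindow, stats@totalWindows, stats@expectedHits,
              stats@informationBits, stats@pAnyHit, stats@pUnique))
}

setMethod("show", "MatchStatistics", function(object) {
  cat("MatchStatistics\n")
  cat(sprintf("  p(window matches):   %.6g\n", object@pWindow))
  cat(sprintf("  windows scanned:     %.6g\n", object@totalWindows))
  cat(sprintf("  expected hits:       %.6g\n", object@expectedHits))
  cat(sprintf("  information content: %.4g bits\n", object@informationBits))
  cat(sprintf("  P(>=1 chance hit):   %.6g\n", object@pAnyHit))
  cat(sprintf("  P(no chance hit):    %.6g\n", object@pUnique))
  invisible(object)
})
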