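## Internal helpers.

## Coerce sequences (AAString, AAStringSet, character) to a named character
## vector of residue strings.
asResidueStrings <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq1"
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out)))
      names(out) <- paste0("seq", seq_along(out))
  } else {
    stop("sequences must be an AAStringSet, AAString or character vector")
  }
  out
}

## Single sequence as one residue string.
asResidueString <- function(x) {
  s <- asResidueStrings(x)
  if (length(s) != 1L) stop("expected a single sequence")
  unname(s)
}

## Draw n i.i.d. residues from a background model, as a single string.
randomResidues <- function(n, bg = uniformBackground()) {
  paste(sample(AA20, n, replace = TRUE, prob = bgFrequencies(bg)),
        collapse = "")
}

## Euclidean distance matrix between two coordinate matrices (n x 3, m x 3).
crossDistances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
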