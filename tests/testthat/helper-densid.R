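## Shared test helpers: independent oracles and random-case generators.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## ---- independent regex scanning oracle ----------------------------------
## Builds a PCRE lookahead from a list of residue classes and scans with
## gregexpr; shares no code with the package's bitmask scanner.

regexFromClasses <- function(classes, reverse = FALSE, ilEquivalent = FALSE) {
  if (reverse) classes <- rev(classes)
  parts <- vapply(classes, function(s) {
    if (length(s) == 20L) return(".")
    if (ilEquivalent && any(c("I", "L") %in% s)) s <- union(s, c("I", "L"))
    paste0("[", paste(sort(s), collapse = ""), "]")
  }, character(1))
  paste0("(?=", paste(parts, collapse = ""), ")")
}

oracleScan <- function(classes, seqs, reverse = FALSE, ilEquivalent = FALSE) {
  rx <- regexFromClasses(classes, reverse, ilEquivalent)
  m <- length(classes)
  out <- list()
  for (k in seq_along(seqs)) {
    g <- gregexpr(rx, seqs[[k]], perl = TRUE)[[1L]]
    starts <- as.integer(g)
    starts <- starts[starts > 0 & starts + m - 1L <= nchar(seqs[[k]])]
    if (length(starts))
      out[[length(out) + 1L]] <- data.frame(
        id = names(seqs)[[k]], start = starts, end = starts + m - 1L,
        match = substring(seqs[[k]], starts, starts + m - 1L),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Random class list: wildcards, singletons and small classes mixed.
randomClasses <- function(m) {
  lapply(seq_len(m), function(i) {
    k <- sample(c(1L, 1L, 2L, 3L, 6L, 20L), 1L)
    if (k == 20L) AA else sort(sample(AA, k))
  })
}

classesToText <- function(classes) {
  paste(vapply(classes, function(s) {
    if (length(s) == 20L) "X"
    else if (length(s) == 1L) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

randomProteome <- function(nseq, len) {
  seqs <- vapply(seq_len(nseq), function(i)
    paste(sample(AA, len, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("r%03d", seq_len(nseq))
  seqs
}

## ---- fixture writers ----------------------------------------------------

writeTempFasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

## Toy two-chain structure (tripeptides straddling a 4.5 A cutoff) used by
## several structure tests; returns paths plus the atom table.
toyInterfaceFixture <- function(displacement = c(0, 0, 4), waters = NULL) {
  pdb <- tempfile(fileext = ".pdb")
  cif <- tempfile(fileext = ".cif")
  fix <- generateToyStructure(list(A = "GAS", B = "VAL"),
                              displacement = displacement, waters = waters,
                              pdbPath = pdb, cifPath = cif)
  list(pdb = pdb, cif = cif, atoms = fix$atoms)
}

## Brute-force interface oracle on a toy atom table: a residue's side chain
## is in the interface iff any of its non-backbone heavy atoms is within
## cutoff of any heavy atom of the other chain.
oracleInterface <- function(atoms, chainA, chainB, cutoff) {
  bb <- c("N", "CA", "C", "O", "OXT")
  prot <- atoms[atoms$resid != "HOH", ]
  res <- unique(prot[, c("chain", "resno", "resid")])
  res <- res[res$chain %in% c(chainA, chainB), ]
  res$inInterface <- vapply(seq_len(nrow(res)), function(i) {
    self <- prot[prot$chain == res$chain[i] & prot$resno == res$resno[i] &
                   !(prot$elety %in% bb), , drop = FALSE]
    if (nrow(self) == 0L) return(FALSE)
    other_chain <- if (res$chain[i] == chainA) chainB else chainA
    other <- prot[prot$chain == other_chain, , drop = FALSE]
    for (a in seq_len(nrow(self))) {
      d <- sqrt((other$x - self$x[a])^2 + (other$y - self$y[a])^2 +
                  (other$z - self$z[a])^2)
      if (any(d <= cutoff)) return(TRUE)
    }
    FALSE
  }, logical(1))
  res
}

## Brute-force digestion oracle: enumerate cleavage intervals directly.
oracleDigest <- function(seq, maxMissed, enzyme = c("F", "W", "Y", "L", "M"),
                         noP = TRUE) {
  res <- strsplit(seq, "")[[1L]]
  L <- length(res)
  sites <- integer(0)
  for (i in seq_len(max(0L, L - 1L))) {
    if (res[i] %in% enzyme && !(noP && res[i + 1L] == "P"))
      sites <- c(sites, i)
  }
  bounds <- c(0L, sites, L)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in i:min(length(bounds) - 1L, i + maxMissed)) {
      out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[j + 1L], j - i)
    }
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end", "missed")
  df[order(df$start, df$end), ]
}

## Numeric helix-trace oracle: stack rungs, unwrap the rotation angle, and
## interpolate the axial position where the cross-section has turned 180 deg.
oracleCrossover <- function(twist, rise, nRungs = 100000L) {
  k <- 0:nRungs
  ang <- abs(twist) * k          # unwrapped rotation in degrees
  z <- rise * k
  i <- which(ang >= 180)[1L]
  if (is.na(i)) stop("trace too short")
  ## linear interpolation between rungs i-1 and i
  f <- (180 - ang[i - 1L]) / (ang[i] - ang[i - 1L])
  z[i - 1L] + f * (z[i] - z[i - 1L])
}
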