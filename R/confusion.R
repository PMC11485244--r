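## Resolution-tiered confusion model: simulating the derivation of a
## degenerate pattern from side-chain density, and identification-recovery
## experiments on synthetic decoy proteomes.

#' Construct a confusion model
#'
#' @param tiers list of partitions of the 20-residue alphabet, ordered from
#'   best-resolved to worst. Singleton classes may be omitted from a
#'   partition specification; residues not mentioned are filled in as
#'   singletons. Tiers must refine (classes only grow).
#' @param tierProbabilities sampling weight per tier used when
#'   [derivePattern()] or [simulateRecovery()] draws a tier per position;
#'   normalized to sum to 1. Default: uniform over tiers.
#' @return a [ConfusionModel-class].
#' @export
confusionModel <- function(tiers, tierProbabilities = NULL) {
  tiers <- lapply(tiers, function(partial) {
    partial <- lapply(partial, function(cl) sort(unique(cl)))
    mentioned <- unlist(partial)
    if (anyDuplicated(mentioned))
      stop("a residue appears in two classes of the same tier")
    c(partial, as.list(setdiff(AA20, mentioned)))
  })
  if (is.null(tierProbabilities))
    tierProbabilities <- rep(1 / length(tiers), length(tiers))
  tierProbabilities <- tierProbabilities / sum(tierProbabilities)
  new("ConfusionModel", tiers = tiers, tierProbabilities = tierProbabilities)
}

#' Default resolution-tier model
#'
#' Five tiers emulating how side-chain ambiguity grows as local resolution
#' degrades: (1) every residue distinguishable; (2) the classic close pairs
#' S/A, I/L, N/Q, E/D merge; (3) classes grow to S/A/G, T/V, N/M/Q, E/D/R/K,
#' W/F (branched/aromatic/acid-amide shapes); (4) three coarse
#' physicochemical groups (small, polar/charged, aromatic/aliphatic-large);
#' (5) a single class, i.e. a wildcard. The chain is a strict refinement, so
#' a worse tier never contradicts a better one.
#'
#' @param tierProbabilities per-tier sampling weights; the default
#'   `c(0.25, 0.2, 0.3, 0.1, 0.15)` roughly mirrors how often singleton,
#'   small-class, mid-class and wildcard positions occur in a well-resolved
#'   (~2.8 Angstrom) amyloid map.
#' @return a [ConfusionModel-class].
#' @export
defaultConfusionModel <- function(tierProbabilities = c(0.25, 0.2, 0.3, 0.1, 0.15)) {
  confusionModel(list(
    list(),                                                     # singletons
    list(c("S", "A"), c("I", "L"), c("N", "Q"), c("E", "D")),
    list(c("S", "A", "G"), c("T", "V"), c("N", "M", "Q"),
         c("E", "D", "R", "K"), c("W", "F"), c("I", "L")),
    list(c("S", "A", "G", "T", "V", "C", "P"),
         c("N", "M", "Q", "E", "D", "R", "K", "H"),
         c("W", "F", "Y", "I", "L")),
    list(AA20)                                                  # wildcard
  ), tierProbabilities = tierProbabilities)
}

#' Perfect-resolution and no-resolution models
#'
#' `identityConfusionModel()` has a single all-singleton tier (every residue
#' read exactly); `wildcardConfusionModel()` a single all-merged tier (no
#' side chain interpretable).
#' @return a [ConfusionModel-class].
#' @export
identityConfusionModel <- function() confusionModel(list(list()))

#' @rdname identityConfusionModel
#' @export
wildcardConfusionModel <- function() confusionModel(list(list(AA20)))

#' @rdname confusionModel
#' @param model a [ConfusionModel-class].
#' @export
nTiers <- function(model) {
  stopifnot(is(model, "ConfusionModel"))
  length(model@tiers)
}

#' @rdname confusionModel
#' @export
modelTiers <- function(model) {
  stopifnot(is(model, "ConfusionModel"))
  model@tiers
}

setMethod("show", "ConfusionModel", function(object) {
  cat(sprintf("ConfusionModel with %d tier(s)\n", length(object@tiers)))
  for (t in seq_along(object@tiers)) {
    classes <- object@tiers[[t]]
    multi <- classes[vapply(classes, length, integer(1)) > 1L]
    lab <- if (length(multi) == 0L) "all singletons"
           else paste(vapply(multi, function(cl)
             paste0("{", paste(cl, collapse = ""), "}"), character(1)),
             collapse = " ")
    cat(sprintf("  tier %d (P=%.2f): %s\n",
                t, object@tierProbabilities[[t]], lab))
  }
  invisible(object)
})

## Class containing `residue` at tier `t` of `model`.
confusionClass <- function(model, residue, t) {
  classes <- model@tiers[[t]]
  hit <- vapply(classes, function(cl) residue %in% cl, logical(1))
  classes[[which(hit)]]
}

#' Derive a degenerate pattern from a sequence window
#'
#' Simulates reading a stretch of residues out of density: position i of the
#' result is the confusion class that contains residue i at that position's
#' assigned resolution tier. The worst (all-merged) tier yields a wildcard.
#' The derived class always contains the true residue.
#'
#' @param window residue string (or AAString).
#' @param model a [ConfusionModel-class].
#' @param tiers integer vector of tier assignments, one per position
#'   (recycled if length 1). Default: tier 1 for all positions.
#' @return an [AmbiguityPattern-class].
#' @examples
#' derivePattern("GMS", identityConfusionModel())  # pattern "GMS"
#' @export
derivePattern <- function(window, model, tiers = 1L) {
  stopifnot(is(model, "ConfusionModel"))
  w <- asResidueString(window)
  if (!nzchar(w)) stop("window must be non-empty")
  res <- strsplit(w, "", fixed = TRUE)[[1L]]
  bad <- which(!(res %in% AA20))
  if (length(bad))
    stop(sprintf("residue '%s' at window position %d is outside the standard alphabet",
                 res[[bad[[1L]]]], bad[[1L]]))
  tiers <- as.integer(rep_len(tiers, length(res)))
  if (any(tiers < 1L | tiers > length(model@tiers)))
    stop("tier assignment outside the model's tier range")
  newPattern(mapply(function(r, t) confusionClass(model, r, t),
                    res, tiers, SIMPLIFY = FALSE))
}

#' Identification-recovery simulation
#'
#' Measures how often a density-derived pattern identifies its protein
#' uniquely. Each replicate (1) generates a synthetic decoy proteome of
#' `nDecoys` i.i.d. sequences from the background, (2) embeds the true
#' protein, (3) picks a random window of length `m` from the true protein,
#' (4) derives a pattern through the confusion model (tiers fixed or sampled
#' per position), (5) scans the whole proteome, and (6) records whether the
#' true protein is the unique protein with a hit, and whether it is among
#' the hits (it always is, since derived classes contain the true residues).
#'
#' Replicate r uses seed `seed + r`, so results are reproducible bit-for-bit
#' and individual replicates can be re-run in isolation.
#'
#' @param trueProtein a single named sequence (named character, AAString set
#'   of length 1); the name is its identifier.
#' @param m window length.
#' @param model a [ConfusionModel-class].
#' @param nDecoys number of decoy sequences per replicate.
#' @param decoyLength fixed decoy length, or a function(n) returning n
#'   integer lengths (e.g. a log-normal sampler).
#' @param bg background model decoys are drawn from.
#' @param replicates number of replicates.
#' @param seed integer base seed.
#' @param tiers tier assignment passed to [derivePattern()]; `NULL` (default)
#'   samples a tier per position from the model's tier probabilities.
#' @return a [RecoveryResult-class].
#' @export
simulateRecovery <- function(trueProtein, m, model = defaultConfusionModel(),
                             nDecoys = 1000L, decoyLength = 300L,
                             bg = uniformBackground(), replicates = 25L,
                             seed = 1L, tiers = NULL) {
  stopifnot(is(model, "ConfusionModel"))
  tp <- asResidueStrings(trueProtein)
  if (length(tp) != 1L) stop("trueProtein must be a single sequence")
  trueId <- names(tp)
  trueSeq <- unname(tp)
  if (m > nchar(trueSeq)) stop("window length m exceeds the protein length")
  if (replicates < 1L) stop("need at least one replicate")
  if (nDecoys < 0L) stop("nDecoys must be non-negative")
  seed <- as.integer(seed)

  per <- matrix(NA, nrow = replicates, ncol = 2L,
                dimnames = list(NULL, c("unique", "containsTrue")))
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    lens <- if (is.function(decoyLength)) as.integer(decoyLength(nDecoys))
            else rep.int(as.integer(decoyLength), nDecoys)
    if (any(lens < 1L)) stop("decoy lengths must be positive")
    pool <- sample(AA20, sum(lens), replace = TRUE, prob = bgFrequencies(bg))
    ends <- cumsum(lens)
    bigs <- paste(pool, collapse = "")
    decoys <- substring(bigs, c(1L, utils::head(ends, -1L) + 1L), ends)
    names(decoys) <- sprintf("decoy%04d", seq_along(decoys))
    proteome <- c(decoys, stats::setNames(trueSeq, trueId))
    ## random window on the true protein, then a tier per position
    start <- sample.int(nchar(trueSeq) - m + 1L, 1L)
    window <- substring(trueSeq, start, start + m - 1L)
    tierAssign <- if (is.null(tiers))
      sample.int(length(model@tiers), m, replace = TRUE,
                 prob = model@tierProbabilities)
    else tiers
    pat <- derivePattern(window, model, tierAssign)
    hits <- scanProteome(pat, proteome)
    ids <- unique(hits$id)
    per[r, "containsTrue"] <- trueId %in% ids
    per[r, "unique"] <- identical(ids, trueId)
  }
  new("RecoveryResult",
      fractionUnique = mean(per[, "unique"]),
      fractionContainsTrue = mean(per[, "containsTrue"]),
      replicates = as.integer(replicates), seed = seed,
      parameters = list(m = m, nDecoys = nDecoys, decoyLength = decoyLength,
                        tiers = tiers),
      perReplicate = per == 1)
}

#' @rdname simulateRecovery
#' @param result a [RecoveryResult-class].
#' @export
fractionUnique <- function(result) {
  stopifnot(is(result, "RecoveryResult"))
  result@fractionUnique
}

#' @rdname simulateRecovery
#' @export
fractionContainsTrue <- function(result) {
  stopifnot(is(result, "RecoveryResult"))
  result@fractionContainsTrue
}

setMethod("show", "RecoveryResult", function(object) {
  cat(sprintf(
    "RecoveryResult: %d replicate(s), seed %d\n  unique identification: %.3f\n  true protein among hits: %.3f\n",
    object@replicates, object@seed, object@fractionUnique,
    object@fractionContainsTrue))
  invisible(object)
})
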