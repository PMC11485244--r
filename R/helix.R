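## Helical symmetry <-> crossover distance conversions for amyloid filaments.

#' Helical symmetry constructor
#'
#' @param twist degrees of rotation per rung, signed; negative twist denotes
#'   a left-handed filament (the convention used in all outputs of this
#'   package). `0 < |twist| <= 180`.
#' @param rise axial translation per rung in Angstrom; the canonical
#'   cross-beta rung spacing is 4.75 Angstrom.
#' @return a [HelicalSymmetry-class].
#' @examples
#' helicalSymmetry(twist = -1.71, rise = 4.75)
#' @export
helicalSymmetry <- function(twist, rise) {
  new("HelicalSymmetry", twist = as.numeric(twist), rise = as.numeric(rise))
}

#' @rdname helicalSymmetry
#' @param sym a [HelicalSymmetry-class].
#' @export
symTwist <- function(sym) { stopifnot(is(sym, "HelicalSymmetry")); sym@twist }

#' @rdname helicalSymmetry
#' @export
symRise <- function(sym) { stopifnot(is(sym, "HelicalSymmetry")); sym@rise }

#' @rdname helicalSymmetry
#' @export
handedness <- function(sym) {
  stopifnot(is(sym, "HelicalSymmetry"))
  if (sym@twist < 0) "left" else "right"
}

setMethod("show", "HelicalSymmetry", function(object) {
  cat(sprintf(
    "HelicalSymmetry: twist %.4g deg/rung (%s-handed), rise %.4g A/rung\n",
    object@twist, handedness(object), object@rise))
  cat(sprintf("  crossover: %.4g A (%.4g nm), %.4g rungs per crossover\n",
              crossoverFromSymmetry(object), crossoverFromSymmetry(object) / 10,
              rungsPerCrossover(object)))
  invisible(object)
})

#' Crossover distance from twist and rise
#'
#' The crossover is the axial distance over which the filament cross-section
#' rotates by 180 degrees -- the repeat visible in micrographs (about 50 nm
#' for the filaments this package models). With twist in degrees per rung
#' and rise in Angstrom per rung, `crossover = rise * 180 / |twist|`.
#'
#' @param sym a [HelicalSymmetry-class].
#' @return crossover distance in Angstrom.
#' @examples
#' crossoverFromSymmetry(helicalSymmetry(-1.71, 4.75))  # ~500 A = 50 nm
#' @export
crossoverFromSymmetry <- function(sym) {
  stopifnot(is(sym, "HelicalSymmetry"))
  sym@rise * 180 / abs(sym@twist)
}

#' Twist from an observed crossover distance
#'
#' Inverse of [crossoverFromSymmetry()]: `|twist| = rise * 180 / crossover`,
#' signed by the stated handedness.
#'
#' @param crossover crossover distance in Angstrom (`>= rise`).
#' @param rise rise per rung in Angstrom.
#' @param hand `"left"` (negative twist) or `"right"`.
#' @return a [HelicalSymmetry-class].
#' @examples
#' twistFromCrossover(500, 4.75, "left")  # twist -1.71 deg
#' @export
twistFromCrossover <- function(crossover, rise, hand = c("left", "right")) {
  hand <- match.arg(hand)
  if (!is.numeric(crossover) || crossover < rise)
    stop("crossover must be >= rise (at most 180 degrees of twist per rung)")
  twist <- rise * 180 / crossover
  helicalSymmetry(if (hand == "left") -twist else twist, rise)
}

#' @rdname crossoverFromSymmetry
#' @export
rungsPerCrossover <- function(sym) {
  stopifnot(is(sym, "HelicalSymmetry"))
  180 / abs(sym@twist)
}
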