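---
title: "Identifying proteins from cryo-EM side-chain density: methods and design"
author: "densid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying proteins from cryo-EM side-chain density: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densid)
```

## The problem

A cryo-EM reconstruction of an amyloid filament sometimes contains a chain
that cannot be assigned to any expected protein. At ~3 Å resolution the
backbone and many side chains are visible, but side-chain density does not
pin down every residue: a well-resolved tryptophan is unmistakable, while
serine versus alanine, or the acid/amide pairs, may be indistinguishable.
What the map supports is therefore not a sequence but a *degenerate
pattern*: an ordered list of residue classes, one per position, with
wildcards where the density is uninterpretable. The motivating case for
this package is the heteromeric ANXA11–TDP-43 filament of FTLD-TDP type C,
where an 11-position pattern read off the density,

```
G[NMQ]X[SA][EDRKQN]M[SA][SAG]X[WF][SAG]
```

sufficed to identify the unknown chain as annexin A11 by a proteome search
that returned a single protein. `densid` implements that procedure — the
pattern model, the proteome scanner and the statistics that justify calling
a single hit an identification — together with the chain-level arithmetic
used to characterize such filaments: segment masses, composition,
in-silico chymotryptic digestion, helical geometry and interface
hydrophobicity.

## The pattern model and its statistics

A pattern of length $m$ is a list of residue sets $S_1,\dots,S_m$, each a
non-empty subset of the 20-residue alphabet; $|S_i| = 20$ is a wildcard
(`X`). Under an i.i.d. background with residue frequencies $f_a$, a random
window matches with probability

$$p = \prod_{i=1}^{m} \sum_{a \in S_i} f_a ,$$

and a proteome with $N = \sum_j \max(0, L_j - m + 1)$ windows yields an
expected number of chance matches $E = pN$. Treating chance matches as
Poisson, the probability that a search returns *no* chance hit is
$e^{-E}$; the information content $-\log_2 p$ is additive over positions.
For the 11-position pattern above, $p = 1296/20^9 \approx 2.5\times10^{-9}$
(28.6 bits), so even at the scale of a combined reference-proteome search
($N \approx 10^7$) the expected number of chance hits is only ~0.03 and a
single hit is a confident identification. These quantities assume
independence between positions and between windows; overlapping windows are
weakly dependent, but at $E \ll 1$ the Poisson approximation is
conservative enough for this use.

The background defaults to uniform ($f_a = 0.05$) because no null model is
canonical for this task; an empirical background computed from the scanned
proteome is available (`empiricalBackground()`), and for LCD-rich proteomes
it is the more demanding null since the classes in density-derived patterns
are biased toward small residues that are over-represented there.

Grammar decisions: the bracket syntax is exactly the form in which such
motifs are printed; a PROSITE converter (`prositeToBracket()`) is provided
as a convenience. `X` is the only wildcard token and lowercase input is
rejected rather than silently upcased, so a stray `x` in a hand-typed
pattern cannot change its meaning. Negated classes are not supported:
density suggests what a residue *could* be, not what it is not.

## The scanner

`scanProteome()` tests every window of every sequence and reports all
overlapping matches with 1-based inclusive coordinates. Matching uses
per-position 20-bit residue masks with one extra bit for non-standard
subject letters (B, Z, J, U, O, X): these never satisfy a non-wildcard
position — conservative matching avoids false identifications — but do
satisfy wildcards. `*` and gap characters are stripped at read time with a
logged count. Two flags address physical ambiguities of the source data:
`reverse` scans the pattern back-to-front (chain direction can be uncertain
in intermediate-resolution density), and `ilEquivalent` makes I and L
interchangeable (their side chains are isomers that density cannot
separate). I/L equivalence is off by default because a printed motif that
distinguishes M from I/L-like density has evidently already committed to
specific assignments. The test suite holds the scanner to exact hit-list
equality with an independently constructed regular-expression oracle on
randomized pattern/proteome pairs.

## The confusion model

To ask *when* this identification procedure works, the package abstracts
local map quality into a `ConfusionModel`: an ordered list of partitions of
the alphabet. Tier 1 (best density) has every residue in its own class;
later tiers merge classes; the last tier is a single class, i.e. a
wildcard. Partitions must *refine* along the chain — a worse tier never
contradicts a better one — and `derivePattern()` simply replaces each
residue of a true window by its class at that position's tier, so the
derived class always contains the true residue (tested as a soundness
property).

The default five-tier chain is: singletons; {S,A}, {I,L}, {N,Q}, {E,D};
{S,A,G}, {T,V}, {N,M,Q}, {E,D,R,K}, {W,F}, {I,L}; three coarse
physicochemical groups; one class. This choice mirrors the classes that
occur in practice in well-resolved amyloid maps, but one point is worth
making explicit: the printed motif above contains both `[NMQ]` and
`[EDRKQN]`, and no single refining chain of partitions can produce both
(they overlap in N and Q without either containing the other, since M is
absent from the larger class). Those two classes arise from different
local-density judgements — acid/amide-shaped versus branched-amide-shaped
blobs — which is precisely why the model assigns tiers *per position*,
either fixed or sampled from per-tier probabilities (default
`c(0.25, 0.2, 0.3, 0.1, 0.15)`, roughly the mix of singleton, small-class,
mid-class and wildcard positions seen in a ~2.8 Å map). The default chain
is a reconstruction, not a measured instrument response, and is fully
configurable via `confusionModel()`.

`simulateRecovery()` measures identification performance: each replicate
generates a decoy proteome from the background, embeds the true protein,
picks a random window, derives a pattern, scans, and records whether the
true protein is the unique protein hit. One integer seed governs
everything, with replicate $r$ seeded at `seed + r`, so results are
bit-for-bit reproducible and individual replicates can be re-run. The
default study condition — 1,000 decoys of 300 residues, window length 11 —
matches the scale at which the procedure should essentially always succeed
under perfect resolution ($E_{\text{bg}} \approx 3\times10^5 \cdot 20^{-11}
\approx 4\times10^{-5}$), and the suite also checks the opposite regime:
short exact windows, where the unique-identification rate must converge to
the Poisson prediction $e^{-E}$.

## What the synthetic data do and do not show

The generator draws i.i.d. residues, so decoys have no repeats, no
homologues, no low-complexity tracts and no shared evolutionary history.
Real proteomes violate all of these, and in the direction that makes
identification *harder*: LCD-like compositions concentrate probability
mass on the very classes that density-derived patterns use. Passing
recovery tests on uniform decoys therefore demonstrates the machinery and
its statistics, not a guarantee about any particular real proteome; the
empirical-background option exists to re-score a pattern against the
composition actually scanned. The package ships the two fold-region
fragments (ANXA11 37–74, TDP-43 273–363, in full-length UniProt numbering
via per-record offsets) rather than full-length chains; full-length demos
use generated stand-ins that are labelled synthetic.

## Chain-level arithmetic

Masses use the standard average residue-mass table by default (gel and
immunoblot kDa estimates are average-mass scale), with monoisotopic masses
and fixed carbamidomethyl-Cys available. A segment's mass is the residue
sum plus one water; additivity up to shared waters is a tested invariant.
The two alternative N-termini of the TDP-43 chain (G282 and G284) are both
computed and reported side by side — at average masses they give 6.23 and
6.03 kDa — because the density supports either start.

`fragmentBoundaryFromMass()` inverts a cumulative mass profile: given an
apparent fragment mass (such as the ~22 kDa N-terminal annexin fragment
seen on immunoblots) it returns the boundary residue whose cumulative mass
is closest to the target, ties broken toward the smaller index. This is an
*estimate* — gel migration is not an exact mass measurement and the true
cleavage site is unknown — and the returned residual makes the uncertainty
explicit.

Chymotryptic digestion defaults to specificity {F, W, Y, L, M} with
cleavage suppressed before proline; the enzyme's specificity set is a
convention, not a constant of nature, so both are configurable. Peptides
are enumerated for all spans of at most `maxMissed` internal sites (the MS
search regime that allows missed cleavages; three is the conventional
ceiling used here as default), and `foldCoverage()` reports how many
peptides overlap an ordered-fold span and what fraction of its positions
they cover.

## Helical geometry

Twist $\theta$ (degrees per rung, negative = left-handed, a convention
stated in every output) and rise $h$ (Å per rung) relate to the crossover
distance visible in micrographs by $d = 180h/|\theta|$. The canonical
cross-β rise of 4.75 Å is used as a documented default only. A numeric
oracle in the tests stacks rungs, unwraps the rotation and interpolates
the 180° point, agreeing with the closed form to 1e-6 relative. For a
~50 nm crossover at 4.75 Å rise, the implied twist is −1.71° and one
crossover stacks ~105 rungs; these are consistency computations around the
observable, not refined symmetry parameters.

## Interfaces in atomic models

`interfaceSideChains()` uses a plain geometric criterion: a residue's side
chain (all heavy atoms beyond the backbone, CB included) participates in
the interface when any of its atoms lies within the cutoff of any heavy
atom of the other range. The default 4.5 Å is a common van der Waals
contact convention; because published statements like "15 side chains
participate, 12 hydrophobic" rarely state their criterion, the report
exposes the cutoff and the recommended practice is to sweep 4.0–5.0 Å and
check stability (monotonicity of the interface set in the cutoff is a
tested invariant). Glycine is never counted; the default hydrophobic set
is {A, V, L, I, M, F, W, C, P} with tyrosine classified polar-aromatic,
both configurable. Hydrogen bonds are called by donor–acceptor heavy-atom
distance (≤3.5 Å default) plus a D–H···A angle test (≥120°) only when the
model actually contains the donor hydrogen — deposited cryo-EM models
usually do not, in which case the angle is reported as `NA` and distance
decides. Alternate conformers keep the highest occupancy; insertion codes
are preserved. Only a single molecular layer is analyzed; rung-stacking
interactions along the helical axis are out of scope.

## Numerical and testing choices

Probability assertions use 1e-12 relative tolerance; the information
content is computed from per-position logs, so the algebraic identity with
$-\log_2 p$ is exact. Ties in boundary estimation break toward the smaller
index; hits sort by record order then start. Monte-Carlo checks in the
test suite are stratified per position (class-mass estimates multiplied,
delta-method standard error, 3-SE acceptance) rather than naive window
sampling, which would need $\gg 10^8$ draws at $p \sim 10^{-9}$. Problem
sizes in the shipped tests and the acceptance script — a 1.1×10⁷-window
uniform proteome for the chance-hit check, 1,000–2,000 decoy sequences for
recovery and identification, 100 randomized oracle-equivalence pairs —
were chosen as the smallest scales at which each claim is actually
informative.

## Limitations

The simulator abstracts density quality as per-position tiers; it does not
process maps, and nothing here validates a map–model fit. The uniqueness
statistics assume an i.i.d. background and will overstate confidence for
proteomes with strong compositional bias unless the empirical background
is used. The digestion model knows nothing about detectability,
retention or modification beyond fixed carbamidomethyl-Cys. The interface
criterion is distance-only; no buried-surface-area or energy model is
implied.
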