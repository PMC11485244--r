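# densid

Protein identification from cryo-EM side-chain density by degenerate motif
scanning, with companion analyses for heteromeric amyloid filaments.

## The problem

High-resolution cryo-EM maps of patient-derived amyloid filaments sometimes
contain an ordered chain that belongs to no expected protein. At ~3 Å the
side-chain densities narrow each position down to a residue *class* rather
than a single residue — a tryptophan is unambiguous, serine/alanine or the
acid/amide residues often are not. The resulting degenerate pattern, written
in bracket syntax such as

```
G[NMQ]X[SA][EDRKQN]M[SA][SAG]X[WF][SAG]
```

can be searched against reference proteomes; when it returns a single
protein, the unknown chain is identified. This is the procedure that
revealed annexin A11 as the second protein in the heteromeric ANXA11–TDP-43
filaments of FTLD-TDP type C. `densid` is for structural biologists who
want to run and assess this kind of identification, and to do the
surrounding quantitative bookkeeping on the filament: segment masses and
composition, in-silico chymotryptic digestion and fold coverage, helical
twist/rise/crossover geometry, and interface hydrophobicity from PDB/mmCIF
models.

## The model

A pattern of length *m* is a list of residue sets *S₁…Sₘ* (a set of size 20
is the wildcard `X`). Under an i.i.d. background with residue frequencies
*f(a)* (uniform by default, empirical optional):

- match probability of one window: *p = ∏ᵢ Σ₍a∈Sᵢ₎ f(a)*
- expected chance hits in *N* windows: *E = pN*
- information content: *−log₂ p* bits (additive over positions)
- probability the search is background-clean (Poisson): *P(unique) = e⁻ᴱ*

The scanner uses per-position residue bitmasks, reports all overlapping
hits with 1-based coordinates, never lets non-standard letters (B, Z, J, U,
O, X) satisfy a non-wildcard position, and offers reversed-pattern and
I/L-equivalent scanning for the physical ambiguities of density. A
resolution-tiered confusion model simulates deriving patterns from density
and measures unique-identification rates on seeded synthetic decoy
proteomes.

## Worked example

```r
library(densid)

motif <- parsePattern("G[NMQ]X[SA][EDRKQN]M[SA][SAG]X[WF][SAG]")
motif
#> AmbiguityPattern of length 11: G[MNQ]X[AS][DEKNQR]M[AS][AGS]X[FW][AGS]

expectedHits(motif, totalWindows = 1.1e7)
#> MatchStatistics
#>   p(window matches):   2.53125e-09
#>   windows scanned:     1.1e+07
#>   expected hits:       0.0278438
#>   information content: 28.56 bits
#>   P(>=1 chance hit):   0.0274597
#>   P(no chance hit):    0.97254

## embed the shipped annexin LCD fragment among 2,000 decoys and search
fr <- foldRegionSequences()
proteome <- generateSyntheticProteome(2000, len = 400, seed = 42,
                                      embed = fr$ANXA11$sequence)
hits <- scanProteome(motif, proteome)
hits
#>                id start end       match
#> 1 embedded|ANXA11    20  30 GMAANMSGTFG
countDistinctProteins(hits)
#> [1] 1
```

The single hit lands at residues 56–66 of the annexin chain
(`start + offset − 1` with the fragment's offset of 37), inside the
L39–Y74 span that forms the ordered fold. The pattern's 28.6 bits mean
that even ~10⁷ background windows are expected to produce only ~0.03
chance matches, so a single hit is an identification, not a coincidence.
The companion arithmetic ties the structure to gel observations and
micrographs:

```r
segmentMass(segmentSpec("ANXA11", 39, 74), fr$ANXA11$sequence,
            offset = fr$ANXA11$offset)
#> [1] 3805.179        # ~3.8 kDa ordered annexin segment

crossoverFromSymmetry(helicalSymmetry(twist = -1.71, rise = 4.75))
#> [1] 500             # Angstrom: a ~50 nm left-handed crossover
```

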