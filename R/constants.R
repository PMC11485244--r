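## Shared alphabets, mass tables and residue classifications.

## The 20 standard amino acids, alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Letters that may occur in subject sequences but are not standard residues.
## They never satisfy a non-wildcard pattern position (conservative matching)
## but do satisfy a wildcard.
AA_NONSTANDARD <- c("B", "Z", "J", "U", "O", "X")

## Average and monoisotopic residue masses (Da), i.e. the mass each residue
## contributes inside a peptide chain; add one water for a free peptide.
RESIDUE_MASS_AVERAGE <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760)

RESIDUE_MASS_MONO <- c(
  A =  71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G =  57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P =  97.05276,
  S =  87.03203, T = 101.04768, V =  99.06841, W = 186.07931, Y = 163.06333)

WATER_MASS <- c(average = 18.01528, monoisotopic = 18.010565)

## Carbamidomethylation of cysteine (iodoacetamide), fixed-modification mass.
CAM_MASS <- c(average = 57.0513, monoisotopic = 57.02146)

## Default hydrophobic side-chain set for interface summaries. Tyrosine is
## treated as polar aromatic; glycine has no side chain and is never counted.
HYDROPHOBIC_DEFAULT <- c("A", "V", "L", "I", "M", "F", "W", "C", "P")

## Three-letter -> one-letter residue codes for structure parsing.
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y")

## Backbone heavy-atom names; everything else heavy is side chain (CB included).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## Water / common solvent residue names in deposited models.
SOLVENT_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
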