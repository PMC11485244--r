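>ANXA11 region=37-74 human annexin A11 (UniProt P50995) N-terminal LCD fragment, full-length numbering
IGLDNVATYAGQFNQDYLSGMAANMSGTFGGANMPNLY
>TDP43 region=273-363 human TDP-43 (UniProt Q13148) C-terminal LCD fragment, full-length numbering
SGRFGGNPGGFGNQGGFGNSRGGGAGLGNNQGSNMGGGMNFGAFSINPAMMAAAQAALQS
SWGMMGMLASQQNQSGPSGNNQNQGNMQREP
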