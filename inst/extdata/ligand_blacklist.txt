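# Residue codes never treated as specific ligands.
# One code per line; '#' starts a comment.

# water
HOH
DOD
WAT
H2O

# monoatomic ions
NA
CL
K
MG
CA
ZN
MN
FE
CU
NI
CO
CD
HG
IOD
BR
F

# cryoprotectants, solvents and buffer artifacts
GOL
EDO
PEG
PG4
DMS
ACT
SO4
PO4
FMT
MPD
TRS
EPE
MES
BME
NO3
IMD
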