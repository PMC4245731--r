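aa,hydropathy,polarity,charge
ALA,1.8,0.00,neutral
ARG,-4.5,52.00,positive
ASN,-3.5,3.38,neutral
ASP,-3.5,49.70,negative
CYS,2.5,1.48,neutral
GLN,-3.5,3.53,neutral
GLU,-3.5,49.90,negative
GLY,-0.4,0.00,neutral
HIS,-3.2,51.60,positive
ILE,4.5,0.13,neutral
LEU,3.8,0.13,neutral
LYS,-3.9,49.50,positive
MET,1.9,1.43,neutral
PHE,2.8,0.35,neutral
PRO,-1.6,1.58,neutral
SER,-0.8,1.67,neutral
THR,-0.7,1.66,neutral
TRP,-0.9,2.10,neutral
TYR,-1.3,1.61,neutral
VAL,4.2,0.13,neutral
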