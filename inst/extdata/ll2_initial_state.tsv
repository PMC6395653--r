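# Default inlet blood composition (role C0) and intracellular initial
# concentrations (role m0), both mM.  Blood drugs enter via scenario dosing.
species	role	value
EGLC	C0	8.0
EGLN	C0	0.8
EGLU	C0	0.25
ALA	C0	0.5
ARG	C0	0.25
ASN	C0	0.25
ASP	C0	0.15
GLY	C0	0.5
HIS	C0	0.15
ILE	C0	0.25
LEU	C0	0.3
LYS	C0	0.35
SER	C0	0.3
THR	C0	0.3
TYR	C0	0.15
VAL	C0	0.35
LAC	C0	1.5
NH4	C0	0.05
CO2	C0	1.2
H2O	C0	0
DICLO	C0	0
HCIT	C0	0
LA	C0	0
MET	C0	0
G6P	m0	0.1
F6P	m0	0.05
GAP	m0	0.02
PEP	m0	0.02
PYR	m0	0.3
R5P	m0	1.0
ACCOAm	m0	0.02
ACCOAc	m0	0.02
CIT	m0	0.3
AKG	m0	0.3
SUCCOA	m0	0.02
SUC	m0	0.5
FUM	m0	0.1
MAL	m0	0.3
OXA	m0	0.005
GLU	m0	0.5
PALM	m0	0.5
ATP	m0	3.0
ADP	m0	1.0
AMP	m0	0.3
Pi	m0	5.0
NAD	m0	3.2
NADH	m0	0.8
NADP	m0	0.02
NADPH	m0	0.08
FAD	m0	0.1
FADH2	m0	0.05
COA	m0	0.5
LAC	Cinit	2.5
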