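# LL/2 central-carbon-metabolism reconstruction: metabolite declarations
# compartment: blood = tumor capillary microenvironment (perfused), cell = intracellular (single pool)
id	name	compartment	units
EGLC	Extracellular glucose	blood	mM
EGLN	Extracellular glutamine	blood	mM
EGLU	Extracellular glutamate	blood	mM
ALA	Extracellular alanine	blood	mM
ARG	Extracellular arginine	blood	mM
ASN	Extracellular asparagine	blood	mM
ASP	Extracellular aspartate	blood	mM
GLY	Extracellular glycine	blood	mM
HIS	Extracellular histidine	blood	mM
ILE	Extracellular isoleucine	blood	mM
LEU	Extracellular leucine	blood	mM
LYS	Extracellular lysine	blood	mM
SER	Extracellular serine	blood	mM
THR	Extracellular threonine	blood	mM
TYR	Extracellular tyrosine	blood	mM
VAL	Extracellular valine	blood	mM
LAC	Extracellular lactate	blood	mM
NH4	Extracellular ammonia	blood	mM
CO2	Carbon dioxide	blood	mM
H2O	Water	blood	mM
DICLO	Extracellular diclofenac	blood	mM
HCIT	Extracellular hydroxycitrate	blood	mM
LA	Extracellular lipoic acid	blood	mM
MET	Extracellular metformin	blood	mM
G6P	Glucose-6-phosphate	cell	mM
F6P	Fructose-6-phosphate	cell	mM
GAP	Glyceraldehyde-3-phosphate	cell	mM
PEP	Phosphoenolpyruvate	cell	mM
PYR	Pyruvate	cell	mM
R5P	Ribulose-5-phosphate	cell	mM
ACCOAm	Acetyl-CoenzymeA (mitochondrial pool)	cell	mM
ACCOAc	Acetyl-CoenzymeA (cytosolic pool)	cell	mM
CIT	Citrate	cell	mM
AKG	alpha-ketoglutarate	cell	mM
SUCCOA	Succinyl-CoenzymeA	cell	mM
SUC	Succinate	cell	mM
FUM	Fumarate	cell	mM
MAL	Malate	cell	mM
OXA	Oxaloacetate	cell	mM
GLU	Glutamate	cell	mM
PALM	Palmitate	cell	mM
ATP	Adenosine triphosphate	cell	mM
ADP	Adenosine diphosphate	cell	mM
AMP	Adenosine monophosphate	cell	mM
Pi	Inorganic phosphate	cell	mM
NAD	Nicotinamide adenine dinucleotide (oxidized)	cell	mM
NADH	Nicotinamide adenine dinucleotide (reduced)	cell	mM
NADP	Nicotinamide adenine dinucleotide phosphate (oxidized)	cell	mM
NADPH	Nicotinamide adenine dinucleotide phosphate (reduced)	cell	mM
FAD	Flavin adenine dinucleotide (oxidized)	cell	mM
FADH2	Flavin adenine dinucleotide (reduced)	cell	mM
COA	Coenzyme A (free)	cell	mM
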