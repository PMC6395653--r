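# LL/2 central-carbon-metabolism reconstruction: reactions (one per row)
# equation grammar: "coef ID + coef ID -> coef ID + ..." ("<->" if reversible)
# glycolytic, PPP, TCA, lipogenic, oxidative-phosphorylation and amino-acid lumps
id	equation	reversible	enzyme	notes
VHK	1 EGLC + 1 ATP -> 1 G6P + 1 ADP	FALSE	hexokinase (glucose transport lumped)	diclofenac target
VPGI	1 G6P -> 1 F6P	FALSE	phosphoglucose isomerase	
VPFK	1 F6P + 1 ATP -> 2 GAP + 1 ADP	FALSE	phosphofructokinase + aldolase + TPI	
VGAPDH	1 GAP + 1 NAD + 1 ADP + 1 Pi -> 1 PEP + 1 NADH + 1 ATP	FALSE	GAPDH..enolase lump	
VPK	1 PEP + 1 ADP -> 1 PYR + 1 ATP	FALSE	pyruvate kinase	
VLDH	1 PYR + 1 NADH <-> 1 LAC + 1 NAD	TRUE	lactate dehydrogenase + MCT lump	diclofenac target; negative flux = lactate uptake
VG6PDH	1 G6P + 2 NADP -> 1 R5P + 2 NADPH + 1 CO2	FALSE	oxidative pentose phosphate lump	
VPDH	1 PYR + 1 COA + 1 NAD -> 1 ACCOAm + 1 NADH + 1 CO2	FALSE	pyruvate dehydrogenase complex	alpha-lipoic acid target (activator)
VCS	1 ACCOAm + 1 OXA -> 1 CIT + 1 COA	FALSE	citrate synthase	
VIDH	1 CIT + 1 NAD -> 1 AKG + 1 NADH + 1 CO2	FALSE	aconitase + isocitrate dehydrogenase	
VAKGDH	1 AKG + 1 COA + 1 NAD -> 1 SUCCOA + 1 NADH + 1 CO2	FALSE	alpha-ketoglutarate dehydrogenase	
VSCS	1 SUCCOA + 1 ADP + 1 Pi -> 1 SUC + 1 ATP + 1 COA	FALSE	succinyl-CoA synthetase	
VSDH	1 SUC + 1 FAD -> 1 FUM + 1 FADH2	FALSE	succinate dehydrogenase	
VFUM	1 FUM <-> 1 MAL	TRUE	fumarase	
VMDH	1 MAL + 1 NAD <-> 1 OXA + 1 NADH	TRUE	malate dehydrogenase	
VME	1 MAL + 1 NAD -> 1 PYR + 1 NADH + 1 CO2	FALSE	malic enzyme (NAD-linked, ME2)	
VACL	1 CIT + 1 ATP + 1 COA -> 1 ACCOAc + 1 OXA + 1 ADP + 1 Pi	FALSE	ATP-citrate lyase	hydroxycitrate target
VPALM	8 ACCOAc + 14 NADPH + 7 ATP -> 1 PALM + 8 COA + 14 NADP + 7 ADP + 7 Pi	FALSE	fatty-acid synthesis lump (ACC + FAS)	
Vresp	1 NADH -> 1 NAD + 1 H2O	FALSE	electron transport chain (complex I..IV), O2 implicit	respiration flux
VFADox	1 FADH2 -> 1 FAD + 1 H2O	FALSE	electron transport chain (complex II entry)	
VATPase	1 ADP + 1 Pi -> 1 ATP	FALSE	ATP synthase (chemiosmotic coupling implicit)	metformin target (inhibitor)
VNADleak	1 NADH -> 1 NAD	FALSE	uncoupled NADH oxidation (NAD leak)	metformin target (activator)
VAK	1 ATP + 1 AMP <-> 2 ADP	TRUE	adenylate kinase	
VGLNASE	1 EGLN -> 1 GLU + 1 NH4	FALSE	glutaminase (glutamine transport lumped)	
VGDH	1 GLU + 1 NAD -> 1 AKG + 1 NH4 + 1 NADH	FALSE	glutamate dehydrogenase	
VALATA	1 ALA + 1 AKG <-> 1 PYR + 1 GLU	TRUE	alanine transaminase	
VASPTA	1 ASP + 1 AKG <-> 1 OXA + 1 GLU	TRUE	aspartate transaminase	
VGLNT	1 GLU + 1 NH4 + 1 ATP -> 1 EGLN + 1 AMP + 2 Pi	FALSE	glutamine synthetase (GlnT)	
VHISARGTA	1 HIS + 1 ARG -> 2 GLU + 3 NH4 + 1 CO2	FALSE	histidine/arginine degradation to glutamate (lump)	
VLEUD	1 LEU + 2 COA + 1 NAD -> 2 ACCOAm + 1 NADH + 1 NH4 + 1 CO2	FALSE	leucine degradation lump	
VILED	1 ILE + 2 COA + 2 NAD -> 1 ACCOAm + 1 SUCCOA + 2 NADH + 1 NH4	FALSE	isoleucine degradation lump	
VSERD	1 SER -> 1 PYR + 1 NH4	FALSE	serine dehydratase	
VTHRD	1 THR + 1 COA + 1 NAD -> 1 SUCCOA + 1 NADH + 1 NH4	FALSE	threonine degradation lump	
VATPM	1 ATP -> 1 ADP + 1 Pi	FALSE	non-growth-associated maintenance (cellular ATPases)	
Vgrowth	0.1 ALA + 0.1 ARG + 0.1 ASN + 0.1 ASP + 0.1 GLY + 0.1 HIS + 0.1 ILE + 0.1 LEU + 0.1 LYS + 0.1 SER + 0.1 THR + 0.1 TYR + 0.1 VAL + 0.1 EGLU + 0.2 EGLN + 0.1 G6P + 0.28 R5P + 0.04 PALM + 2 ATP -> 2 ADP + 2.38 Pi	FALSE	biomass synthesis (amino acids + intermediates + palmitate + nucleotide precursor R5P)	biomass reaction
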