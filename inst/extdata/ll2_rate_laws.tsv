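# Default rate laws for the LL/2 reconstruction.
# vmax: forward maximal rate (model flux units/h); vmax_rev: reverse maximal
# rate (0 = irreversible).  km / km_rev: semicolon-separated "species:mM"
# saturation terms for the forward / reverse direction.
reaction_id	vmax	vmax_rev	km	km_rev
VHK	0.075	0	EGLC:1.0;ATP:0.3	
VPGI	0.1	0	G6P:0.5	
VPFK	0.06	0	F6P:0.03;ATP:0.1	
VGAPDH	2.0	0	GAP:5.0;NAD:0.05;ADP:0.01;Pi:0.05	
VPK	0.5	0	PEP:0.05;ADP:0.01	
VLDH	0.15	0.06	PYR:0.3;NADH:0.05	LAC:1.0;NAD:0.2
VG6PDH	0.015	0	G6P:0.01;NADP:0.005	
VPDH	0.02	0	PYR:0.3;COA:0.02;NAD:0.2	
VCS	0.03	0	ACCOAm:0.03;OXA:0.002	
VIDH	0.02	0	CIT:0.2;NAD:0.2	
VAKGDH	0.025	0	AKG:0.3;COA:0.02;NAD:0.2	
VSCS	0.03	0	SUCCOA:0.02;ADP:0.01;Pi:0.05	
VSDH	0.02	0	SUC:0.3;FAD:0.02	
VFUM	0.05	0.05	FUM:0.1	MAL:0.1
VMDH	0.05	0.05	MAL:0.3;NAD:0.1	OXA:0.002;NADH:0.05
VME	0.004	0	MAL:0.3;NAD:0.2	
VACL	0.008	0	CIT:0.2;ATP:0.1;COA:0.02	
VPALM	0.001	0	ACCOAc:0.01;NADPH:0.01;ATP:0.1	
Vresp	0.04	0	NADH:0.05	
VFADox	0.02	0	FADH2:0.02	
VATPase	0.12	0	ADP:0.3;Pi:0.3	
VNADleak	0.0002	0	NADH:0.05	
VAK	0.05	0.05	ATP:0.3;AMP:0.05	ADP:0.5
VGLNASE	0.015	0	EGLN:0.3	
VGDH	0.0275	0	GLU:4.0;NAD:0.2	
VALATA	0.008	0.008	ALA:0.3;AKG:0.3	PYR:0.3;GLU:1.0
VASPTA	0.008	0.008	ASP:0.3;AKG:0.3	OXA:0.002;GLU:1.0
VGLNT	0.001	0	GLU:1.0;NH4:0.5;ATP:0.3	
VHISARGTA	0.002	0	HIS:0.2;ARG:0.2	
VLEUD	0.0015	0	LEU:0.3;COA:0.02;NAD:0.2	
VILED	0.001	0	ILE:0.3;COA:0.02;NAD:0.2	
VSERD	0.002	0	SER:0.3	
VTHRD	0.001	0	THR:0.3;COA:0.02;NAD:0.2	
VATPM	0.3	0	ATP:1.0	
Vgrowth	0.008	0	G6P:0.002;R5P:0.005;PALM:0.005;ATP:0.2;EGLN:0.1;ALA:0.002;ARG:0.002;ASN:0.002;ASP:0.002;GLY:0.002;HIS:0.002;ILE:0.002;LEU:0.002;LYS:0.002;SER:0.002;THR:0.002;TYR:0.002;VAL:0.002;EGLU:0.002	
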