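# Drug-effect annotations: multiplicative modulation of target reaction rates.
# mode inhibit: factor k_half/(k_half + c); mode activate: 1 + c/(k_half + c).
drug	target	mode	k_half
DICLO	VHK	inhibit	0.01
DICLO	VLDH	inhibit	0.01
LA	VPDH	activate	0.01
HCIT	VACL	inhibit	0.05
MET	VATPase	inhibit	13
MET	VNADleak	activate	1.0
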