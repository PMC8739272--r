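ER_stress	endoplasmic-reticulum stress response genes	GADD45A	ATF4	DDIT3	ITPR1
pro_survival	anti-apoptotic BCL2-family and IAP genes	MCL1	BCL2	BCL2L1	BIRC3	CFLAR
pro_apoptotic	pro-apoptotic caspase and BH3-only genes	CASP3	CASP8	BAK1	BAX	AIFM1	PMAIP1	HRK
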