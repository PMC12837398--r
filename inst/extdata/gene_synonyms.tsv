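synonym	canonical
# keys are uppercased with all non-alphanumerics stripped before lookup
ATP6	ATP6
ATPASE6	ATP6
ATPSYNTHASE6	ATP6
ATP8	ATP8
ATPASE8	ATP8
ATPSYNTHASE8	ATP8
COX1	COX1
COXI	COX1
COI	COX1
CO1	COX1
COX2	COX2
COXII	COX2
COII	COX2
CO2	COX2
COX3	COX3
COXIII	COX3
COIII	COX3
CO3	COX3
CYTB	CYTB
CYB	CYTB
COB	CYTB
MTCYB	CYTB
ND1	ND1
NAD1	ND1
NADH1	ND1
ND2	ND2
NAD2	ND2
NADH2	ND2
ND3	ND3
NAD3	ND3
NADH3	ND3
ND4	ND4
NAD4	ND4
NADH4	ND4
ND4L	ND4L
NAD4L	ND4L
NADH4L	ND4L
ND5	ND5
NAD5	ND5
NADH5	ND5
ND6	ND6
NAD6	ND6
NADH6	ND6
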