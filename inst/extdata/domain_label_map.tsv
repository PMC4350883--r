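raw	label
TIR	TIR
TIR_2	TIR
NB-ARC	NB-ARC
NBARC	NB-ARC
NB_ARC	NB-ARC
LRR	LRR
LRRNT	LRR
LRRNT_2	LRR
LRR_1	LRR
LRR_2	LRR
LRR_3	LRR
LRR_4	LRR
LRR_5	LRR
LRR_6	LRR
LRR_7	LRR
LRR_8	LRR
LRR_typical	LRR
B3	B3
NAM	NAC
NAC	NAC
CaM_binding	CAMB
CAMB	CAMB
Pkinase	MAPKKK
MAPKKK	MAPKKK
PAH	PAH
WRKY	WRKY
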