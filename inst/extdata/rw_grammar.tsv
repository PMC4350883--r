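family	pattern	wrky_wildcard
RW1	TIR NB-ARC LRR WRKY(IIe)	0
RW2	TIR NB-ARC LRR WRKY(III) [WRKY(III)]	0
RW3	PAH WRKY(I_NT) WRKY(I_CT) NB-ARC [MAPKKK]	0
RW4	TIR NB-ARC LRR WRKY(III)	0
RW5	[B3] LRR NB-ARC LRR WRKY(IIe)	0
RW6	NB-ARC LRR WRKY(III) [WRKY(III)] [NAC]	0
RW7	LRR WRKY(III) WRKY(IId) CAMB WRKY(IIc)	1
RW8	WRKY(III) NB-ARC LRR	0
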