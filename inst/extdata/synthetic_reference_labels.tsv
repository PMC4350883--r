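id	group
synthref_I_NT	I_NT
synthref_I_CT	I_CT
synthref_IIc	IIc
synthref_IId	IId
synthref_IIe	IIe
synthref_ALGAL_SINGLE	ALGAL_SINGLE
synthref_DIPLOMONAD_TYPE	DIPLOMONAD_TYPE
synthref_IIa	IIa
synthref_IIb	IIb
synthref_III	III
synthref_III_MOSS_VARIANT	III_MOSS_VARIANT
synthref_FUNGAL_TYPE	FUNGAL_TYPE
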