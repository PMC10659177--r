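accession	stem_color	AL_1	AL_2	AL_3	AL_4	AL_5	AL_6	AL_7	AL_8	AL_9	AL_10	n_collections
AU	G	A	A	A	A	A	A	A	A	A	A	14
AM	P	B	B	B	A	B	B	A	B	B	B	22
Hybrid_mAU	G	A	A	A	A	A	A	A	H	H	A	3
Hybrid_mAM_P	P	B	B	B	A	B	B	A	H	H	H	8
Hybrid_mAM_G	G	B	B	B	A	B	B	A	H	H	H	1
AO	P	B	B	B	B	B	A	B	B	B	B	1
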