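name	compartment	target_region	marker_type	class_sizes	class_samples	class_alleles	hrm_offsets	fwd	rev
AL_1	PLASTOME	rpoC2	CODOMINANT_INDEL	A=150;B=135	A=AU|Farm-TB;B=AM|AO|Farm-JB|Farm-SA			AATGGGTGTGATTCGTTGGAC	ATTCATTTTCCCGGAGAGACAG
AL_2	PLASTOME	rpoC2	CODOMINANT_INDEL	A=142;B=127	A=AU|Farm-TB;B=AM|AO|Farm-JB|Farm-SA			TACGGGCCGAACCAAAACA	CGGCATTTTAATACCACCGGGA
AL_3	PLASTOME	rpoB-trnC	CODOMINANT_INDEL	A=196;B=213	A=AU|Farm-TB;B=AM|AO|Farm-JB|Farm-SA			CCGACGGGATACCGAATGAT	AGTTACGCAATTCAAGCGTATTCT
AL_4	PLASTOME	rps18-rpl20	CODOMINANT_INDEL	A=233-236;B=259	A=AU|AM|Farm-TB|Farm-JB|Farm-SA;B=AO			GCTGGTCCTAGAACCCGAAA	GGAGAATGGACTCCGGGAAG
AL_5	PLASTOME	trnV-rps12	CODOMINANT_INDEL	A=190;B=200	A=AU|Farm-TB;B=AM|AO|Farm-JB|Farm-SA			GGGCAAAGGGATTGATCGAGAA	CCTTCTTCCACTCTGCCCC
AL_6	PLASTOME	rps16-trnQ-UUG	CODOMINANT_INDEL	A=155;B=143	A=AU|AO|Farm-TB;B=AM|Farm-JB|Farm-SA			TCTTTAGTCTCCATGTACAGTGTGT	GTTCCATGAAATGTGAATTCTCGC
AL_7	PLASTOME	psbC-trnS-UGA	DOMINANT_SNP	A=184;B=-	A=AU|AM|Farm-TB|Farm-JB|Farm-SA;B=AO			GACCCCACTTAGCTGAGATTTTTAAC	GGTTCGAATCCCTCTCTCTCCT
AL_8	NRDNA	ITS1-5.8S-ITS2	HRM_SNP		A=AU|Farm-TB;B=AM|AO	A=AAT;B=GGC		GTTCGCCGCTTGTGACG	GGAACCCATCCGAAAGGTCA
AL_9	NRDNA	ITS1-5.8S-ITS2	HRM_SNP		A=AU|Farm-TB;B=AM|AO	A=AAT;B=GTA		TGAAGCAAGAAGGAGAGGGG	TGTCGCATTTCGCTACGTTC
AL_10	NRDNA	ITS1-5.8S-ITS2	HRM_SNP		A=AU|Farm-TB;B=AM|AO	A=A;B=G		CTTGGCTCGGTGTGTGGATT	CCAAAGCTAAGAGCGCACAA
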