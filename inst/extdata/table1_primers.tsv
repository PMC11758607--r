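population	gene	forward	reverse	amplicon_bp
str	OCA2	CTCGTCTTGCTTTGATTTGAAA	AGTGGTAAAGTTTTCTGCAGAT	817
bre	OCA2	GTCCTCAGAATCATTCAACTGT	GGAGAAGTGAATTGAAATCCCT	865
bie	OCA2	TTCCTCCATCCTCTAGTATTCC	ACAACAACAACAAAAGTAACCC	972
avu	MX2	TAGTTGGAAGACGGGACAATA	GAAGAAAAGGAATCGAGGAAGT	882
rox	GART	CTGGGCATCTGAAAATAGACAT	GTGTGTGTGTATATAGGCCTTT	878
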