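name	locus	forward	reverse
P609/P610	rbcL	GTAAAATCAAGTCCACCRCG	ATGTCACCACAAACAGAGACTAAAGC
P607/P608	matK	CGTACAGTACTTTTGTGTTTACGAG	ACCCAGTCCATCTGGAAATCTTGGTTC
P646/P647	matK	TAATTTACGATCAATTCATTC	GTTCTAGCACAAGAAAGTCG
P672/P673	rps16-trnQ	GCGTGGCCAAGYGGTAAGGC	GTTGCTTTYTACCACATCGTTT
P674/P675	ITS	CCTTATCATTTAGAGGAAGGAG	TCCTCCGCTTATTGATATGC
P676/P677	trnH-psbA	GTTATGCATGAACGTAATGCTC	CGCGCATGGTGGATTCACAATCC
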