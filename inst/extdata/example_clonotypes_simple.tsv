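cdr3_aa	v_gene	j_gene	count
CASSLGQAYEQYF	TRBV9	TRBJ2-7	412
CASSPGTSGSYNEQFF	TRBV5-1	TRBJ2-1	367
CASRDRGSYGYTF	TRBV6-1	TRBJ1-2	245
CASSFAGTSGMNEQFF	TRBV7-2	TRBJ2-1	198
CASSPNNYEQYF	TRBV18	TRBJ2-7	154
CASKGVSNYGYTF	TRBV19	TRBJ1-2	120
CASSASGTAYGYTF	TRBV19	TRBJ1-2	88
CASSLTGGNQPQHF	TRBV11-2	TRBJ1-5	61
CASSYSTGDEQFF	TRBV6-5	TRBJ2-1	33
CASSESGDTQYF	TRBV10-1	TRBJ2-3	22
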