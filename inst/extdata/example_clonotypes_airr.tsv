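junction_aa	v_call	j_call	duplicate_count
CASSLGQAYEQYF	TRBV9*01	TRBJ2-7*01	412
CASSPGTSGSYNEQFF	TRBV5-1*01	TRBJ2-1*01	367
CASS*GTSGSYNEQFF	TRBV5-1*01	TRBJ2-1*01	12
CASRDRGSYGYTF	TRBV6-1*02	TRBJ1-2*01	245
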