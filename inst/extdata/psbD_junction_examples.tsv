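junction_id	parent_a	parent_b	recombinant	note
30511F_10230R	AGAATAATCCGTTTCGTTTTTTATACTTTCTCCTGAAGTA	AGAGGGTTAAGTTTCGTTTTTTTTTTACTTTCCTTGATAGAT	AGAATAATCCGTTTCGTTTTATACTTTCCTTGATAGAT	recombinant repeat copy carries an internal 2-base deletion; no gap-free decomposition
31900F_17341R	AATTGTAATTAGAGTATTTTTTTTTATTGAT	CTAGAGAAAGAGAGTATTTTTGCAAAGTAAT	AATTGTAATTAGAGTATTTTTGCAAAGTAAT	rpoC2 x trnT-ACC/psbD spacer; exact 11-bp direct repeat
62821F_32700R	CCCGTCAACTAAAAAAAGGGTATAAAAGGA	ACACGCGCCGAAAAAAAGGGGGAACCATAAA	CCCGTCAACTAAAAAAAGGGGGAACCATAAA	trnT-ACC/psbD spacer x petA/psbJ spacer; exact 10-bp direct repeat
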