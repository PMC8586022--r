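contig	position	reference_kmer	read_index	strand	event_index	event_level_mean	event_stdv	event_length	model_kmer	model_mean	model_stdv
ref1	0	AATGC	0	t	0	80.10	1.50	0.00300	AATGC	81.00	1.80
ref1	1	ATGCC	0	t	1	95.40	1.20	0.00250	ATGCC	94.80	1.60
ref1	2	TGCCA	0	t	2	101.90	1.70	0.00400	NNNNN	0.00	0.00
ref1	3	GCCAT	0	t	3	88.30	1.40	0.00350	GCCAT	87.90	1.70
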