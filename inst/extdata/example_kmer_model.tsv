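#example canonical DNA 6mer model (synthetic values)
kmer	level_mean	level_stdv
AAAAAA	98.52000	2.10000
AAAAAT	95.70000	1.90000
AAAAAC	92.31000	2.40000
AAAAAG	101.24000	2.00000
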