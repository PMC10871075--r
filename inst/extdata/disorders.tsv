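name	chrom	start	end	direction	expected_cn
Joubert syndrome 4	2	110852875	110983320	del	1
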