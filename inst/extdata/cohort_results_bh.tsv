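outcome	k_opt	acc	n_sig	sens
IDH1	800	1.0	419	2.2
MGMT	700	1.0	439	2.3
CNEC	NA	NA	0	0.0
MVP	3000	0.951	1405	0.2
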