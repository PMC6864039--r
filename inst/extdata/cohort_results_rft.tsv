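outcome	k_opt	acc	n_sig	sens
IDH1	800	1.0	473	3.2
MGMT	700	0.987	7096	4.8
CNEC	NA	NA	0	0.0
MVP	3000	0.982	14610	9.9
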