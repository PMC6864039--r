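outcome	n_pos	n_neg
IDH1	360	146661
MGMT	93	146938
CNEC	70359	76672
MVP	3122	143909
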