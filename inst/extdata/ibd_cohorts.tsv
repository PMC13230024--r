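study_id	n_HC	n_CD	n_UC
PRJNA324147	53	25	10
PRJNA368966	29	0	32
PRJNA422193	34	34	39
PRJNA431126	34	185	97
PRJNA450340	45	42	39
RISK_PRISM_f	65	362	105
qiita_1629	55	211	286
qiita_2538	360	349	0
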