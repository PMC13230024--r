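study_id	subjects
PRJEB41443	30
PRJNA293971	20
PRJNA306884	20
PRJNA891951	57
PRJNA428736	86
PRJNA560950	30
PRJNA780023	50
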