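individual	population	region
ind001	JP	JP
ind002	JP	JP
ind003	JP	JP
ind004	JP	JP
ind005	HI	HI
ind006	HI	HI
ind007	HI	HI
ind008	ST	WUS
ind009	SD	WUS
ind010	ST	WUS
ind011	SD	WUS
ind012	FL	EUS
ind013	NC	EUS
ind014	MI	EUS
ind015	FL	EUS
ind016	NC	EUS
ind017	MI	EUS
ind018	SP	SP
ind019	SP	SP
ind020	SP	SP
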