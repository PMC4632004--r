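mesenchymal_mrs	stroma-associated mesenchymal master regulators	ZEB1	ZEB2	SNAI2	PRRX1	AEBP1	HOPX
immunoreactive_mrs	stroma-associated immunoreactive master regulators	IRF7	IRF9	IKZF1	IKZF3	BATF	ETV7	BTN3A3	SP140	HCLS1	TFEC
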