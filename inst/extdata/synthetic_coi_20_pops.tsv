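IND007	HK
IND014	HS
IND021	SC
IND034	GY
IND037	YG
IND043	YG
IND051	YG
IND068	GY
IND073	BY
IND074	HS
IND079	BG
IND085	YG
IND089	GY
IND101	HS
IND105	HS
IND106	HS
IND110	BG
IND127	BY
IND129	BY
IND135	YG
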