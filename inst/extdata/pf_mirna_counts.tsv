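id	PF2U	PF2S	PF4U	PF4S
pfo-miR156	341123	268635	406330	418990
pfo-miR157	128016	154352	135041	189687
pfo-mir6	145381	425766	285551	273869
pfo-mir3	34576	31947	24266	29807
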