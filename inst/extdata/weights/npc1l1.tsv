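variant_id	effect_allele	eaf	beta	trait
npc1l1_v001	A	0.0891	-0.775036	npc1l1
npc1l1_v002	C	0.8301	0.844021	npc1l1
npc1l1_v003	G	0.3861	-0.178733	npc1l1
npc1l1_v004	C	0.6451	-0.048302	npc1l1
npc1l1_v005	A	0.0631	-0.41892	npc1l1
npc1l1_v006	G	0.3352	0.486518	npc1l1
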