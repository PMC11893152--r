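variant_id	effect_allele	eaf	beta	trait
activity_v001	G	0.5379	-0.020567	activity
activity_v002	C	0.8208	-0.043785	activity
activity_v003	C	0.6158	-0.007146	activity
activity_v004	G	0.539	-0.007055	activity
activity_v005	A	0.4751	0.041021	activity
activity_v006	A	0.5523	-0.047574	activity
activity_v007	T	0.4798	-0.009997	activity
activity_v008	G	0.0516	0.025283	activity
activity_v009	A	0.6863	-0.017075	activity
activity_v010	G	0.7892	-0.052046	activity
activity_v011	T	0.1718	5.5e-05	activity
activity_v012	T	0.6148	0.042381	activity
activity_v013	C	0.345	0.012489	activity
activity_v014	T	0.3318	0.027196	activity
activity_v015	C	0.4848	0.027883	activity
activity_v016	G	0.7277	-0.04608	activity
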