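variant_id	effect_allele	eaf	beta	trait
bmi_v001	G	0.4386	-0.12357	bmi
bmi_v002	A	0.2778	0.083504	bmi
bmi_v003	G	0.7159	0.133073	bmi
bmi_v004	G	0.0805	-0.03962	bmi
bmi_v005	A	0.906	0.084706	bmi
bmi_v006	C	0.9256	-0.123512	bmi
bmi_v007	C	0.8253	0.104276	bmi
bmi_v008	T	0.5393	-0.279154	bmi
bmi_v009	T	0.7562	-0.18999	bmi
bmi_v010	G	0.6433	-0.048812	bmi
bmi_v011	T	0.7192	-0.041614	bmi
bmi_v012	G	0.1538	0.02907	bmi
bmi_v013	A	0.604	-0.139593	bmi
bmi_v014	A	0.5876	0.185386	bmi
bmi_v015	T	0.6569	0.042735	bmi
bmi_v016	A	0.563	-0.162034	bmi
bmi_v017	C	0.5078	-0.219879	bmi
bmi_v018	T	0.7763	0.268789	bmi
bmi_v019	C	0.2382	0.082171	bmi
bmi_v020	G	0.8132	0.117798	bmi
bmi_v021	A	0.2534	-0.021803	bmi
bmi_v022	T	0.2923	-0.020671	bmi
bmi_v023	C	0.8005	0.110139	bmi
bmi_v024	G	0.1927	-0.055362	bmi
bmi_v025	G	0.1957	0.158576	bmi
bmi_v026	T	0.3455	0.002192	bmi
bmi_v027	C	0.932	0.113272	bmi
bmi_v028	T	0.867	0.288431	bmi
bmi_v029	G	0.2836	-0.171128	bmi
bmi_v030	T	0.4267	0.034821	bmi
bmi_v031	C	0.2505	-0.092646	bmi
bmi_v032	A	0.7444	-0.069368	bmi
bmi_v033	C	0.7573	-0.108823	bmi
bmi_v034	T	0.3691	0.003706	bmi
bmi_v035	G	0.5434	0.05708	bmi
bmi_v036	A	0.3517	0.038057	bmi
bmi_v037	A	0.1888	0.0474	bmi
bmi_v038	T	0.2045	-0.047699	bmi
bmi_v039	T	0.0551	0.071917	bmi
bmi_v040	C	0.8828	-0.171561	bmi
bmi_v041	T	0.8266	0.039862	bmi
bmi_v042	A	0.55	0.075919	bmi
bmi_v043	A	0.8574	-0.224672	bmi
bmi_v044	C	0.7239	0.152846	bmi
bmi_v045	C	0.6065	-0.057361	bmi
bmi_v046	G	0.4687	-0.057973	bmi
bmi_v047	T	0.948	-0.017363	bmi
bmi_v048	A	0.3178	-0.122665	bmi
bmi_v049	T	0.5791	-0.212047	bmi
bmi_v050	A	0.1415	0.022699	bmi
bmi_v051	A	0.9239	0.00945	bmi
bmi_v052	G	0.8371	-0.061603	bmi
bmi_v053	C	0.2617	0.103565	bmi
bmi_v054	C	0.3895	0.291596	bmi
bmi_v055	G	0.0561	-0.01257	bmi
bmi_v056	C	0.7704	-0.091789	bmi
bmi_v057	G	0.0563	0.163841	bmi
bmi_v058	T	0.948	0.119642	bmi
bmi_v059	G	0.3281	-0.042943	bmi
bmi_v060	G	0.8016	-0.113551	bmi
bmi_v061	G	0.4271	0.075399	bmi
bmi_v062	C	0.5844	0.072004	bmi
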