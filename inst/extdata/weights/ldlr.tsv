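variant_id	effect_allele	eaf	beta	trait
ldlr_v001	T	0.9336	0.287448	ldlr
ldlr_v002	T	0.6097	0.735988	ldlr
ldlr_v003	T	0.1334	-0.250655	ldlr
ldlr_v004	G	0.8134	-0.773224	ldlr
ldlr_v005	G	0.4414	-0.174603	ldlr
ldlr_v006	G	0.1137	0.374423	ldlr
ldlr_v007	G	0.2287	-0.05176	ldlr
ldlr_v008	G	0.4364	-0.079363	ldlr
ldlr_v009	T	0.4458	-0.922398	ldlr
ldlr_v010	A	0.7458	0.144994	ldlr
ldlr_v011	C	0.5135	-0.25719	ldlr
ldlr_v012	A	0.1154	-0.019781	ldlr
ldlr_v013	A	0.2018	-0.722592	ldlr
ldlr_v014	T	0.3357	0.020631	ldlr
ldlr_v015	G	0.2023	0.355938	ldlr
ldlr_v016	G	0.6432	0.675792	ldlr
ldlr_v017	T	0.1843	0.567342	ldlr
ldlr_v018	T	0.6033	0.062801	ldlr
ldlr_v019	T	0.9467	0.50408	ldlr
ldlr_v020	T	0.6193	-0.56808	ldlr
ldlr_v021	A	0.0561	0.101493	ldlr
ldlr_v022	G	0.491	1.271854	ldlr
ldlr_v023	T	0.3544	-0.583689	ldlr
ldlr_v024	G	0.5055	0.154102	ldlr
ldlr_v025	G	0.1615	-0.479418	ldlr
ldlr_v026	C	0.1818	-1.729508	ldlr
ldlr_v027	A	0.2317	0.57841	ldlr
ldlr_v028	C	0.7114	0.704006	ldlr
ldlr_v029	C	0.5511	-0.467517	ldlr
ldlr_v030	A	0.6955	0.112825	ldlr
ldlr_v031	A	0.2616	-1.209255	ldlr
ldlr_v032	T	0.7312	-0.343314	ldlr
ldlr_v033	T	0.9242	-0.868365	ldlr
ldlr_v034	G	0.3725	-0.295874	ldlr
ldlr_v035	T	0.8836	-0.343798	ldlr
ldlr_v036	C	0.5919	-0.46101	ldlr
ldlr_v037	C	0.3917	-0.39793	ldlr
ldlr_v038	T	0.0503	-0.559275	ldlr
ldlr_v039	G	0.7979	0.210418	ldlr
ldlr_v040	A	0.3943	0.221353	ldlr
ldlr_v041	T	0.7056	0.626233	ldlr
ldlr_v042	C	0.7234	-0.427509	ldlr
ldlr_v043	A	0.5204	0.01704	ldlr
ldlr_v044	C	0.4693	-0.23873	ldlr
ldlr_v045	T	0.6903	-0.086331	ldlr
ldlr_v046	T	0.8217	0.073172	ldlr
ldlr_v047	C	0.7582	-0.592653	ldlr
ldlr_v048	A	0.0855	-0.683377	ldlr
ldlr_v049	G	0.2094	-0.355329	ldlr
ldlr_v050	G	0.4843	0.708512	ldlr
ldlr_v051	T	0.7593	-0.266239	ldlr
ldlr_v052	A	0.4724	0.013201	ldlr
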