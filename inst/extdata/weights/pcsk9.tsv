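variant_id	effect_allele	eaf	beta	trait
pcsk9_v001	A	0.509	0.663112	pcsk9
pcsk9_v002	G	0.8335	-0.26826	pcsk9
pcsk9_v003	A	0.2728	-0.418628	pcsk9
pcsk9_v004	T	0.3581	-0.410939	pcsk9
pcsk9_v005	A	0.1767	0.149163	pcsk9
pcsk9_v006	A	0.9153	-0.001164	pcsk9
pcsk9_v007	A	0.6809	0.412443	pcsk9
pcsk9_v008	A	0.6709	-0.198866	pcsk9
pcsk9_v009	C	0.2362	-0.140718	pcsk9
pcsk9_v010	C	0.431	0.386602	pcsk9
pcsk9_v011	A	0.8505	0.476377	pcsk9
pcsk9_v012	T	0.6391	-0.100485	pcsk9
pcsk9_v013	A	0.7016	-0.158031	pcsk9
pcsk9_v014	A	0.1874	-0.195611	pcsk9
pcsk9_v015	C	0.2088	-0.505231	pcsk9
pcsk9_v016	T	0.0929	0.989302	pcsk9
pcsk9_v017	T	0.165	-0.487125	pcsk9
pcsk9_v018	T	0.1005	0.286174	pcsk9
pcsk9_v019	A	0.5821	0.642717	pcsk9
pcsk9_v020	A	0.2933	0.582173	pcsk9
pcsk9_v021	C	0.5515	0.491582	pcsk9
pcsk9_v022	T	0.6297	0.214718	pcsk9
pcsk9_v023	G	0.4615	-0.403424	pcsk9
pcsk9_v024	A	0.2924	-0.154764	pcsk9
pcsk9_v025	C	0.9012	-0.061877	pcsk9
pcsk9_v026	C	0.9122	0.413949	pcsk9
pcsk9_v027	T	0.0935	1.005703	pcsk9
pcsk9_v028	T	0.4859	0.30501	pcsk9
pcsk9_v029	G	0.2228	-0.067536	pcsk9
pcsk9_v030	C	0.4218	-0.736885	pcsk9
pcsk9_v031	G	0.5683	0.490427	pcsk9
pcsk9_v032	T	0.1739	-0.424482	pcsk9
pcsk9_v033	T	0.4281	-0.05593	pcsk9
pcsk9_v034	A	0.5768	0.120033	pcsk9
pcsk9_v035	G	0.7259	-0.371135	pcsk9
pcsk9_v036	A	0.115	0.510798	pcsk9
pcsk9_v037	A	0.6786	-0.642233	pcsk9
pcsk9_v038	A	0.2518	0.482172	pcsk9
pcsk9_v039	A	0.7075	-0.117083	pcsk9
pcsk9_v040	T	0.361	0.631676	pcsk9
pcsk9_v041	T	0.4025	0.2791	pcsk9
pcsk9_v042	G	0.866	-0.269176	pcsk9
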