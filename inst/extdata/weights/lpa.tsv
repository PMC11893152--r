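variant_id	effect_allele	eaf	beta	trait
lpa_v001	C	0.6908	-5.397347	lpa
lpa_v002	C	0.6156	-5.32708	lpa
lpa_v003	G	0.8407	3.997453	lpa
lpa_v004	T	0.9149	0.517832	lpa
lpa_v005	A	0.1891	4.482918	lpa
lpa_v006	A	0.7149	5.130171	lpa
lpa_v007	A	0.5872	1.459496	lpa
lpa_v008	A	0.3752	-8.262227	lpa
lpa_v009	C	0.736	-6.836294	lpa
lpa_v010	G	0.7991	-2.338851	lpa
lpa_v011	T	0.7225	-1.508677	lpa
lpa_v012	T	0.6783	6.553546	lpa
lpa_v013	G	0.7943	-2.267674	lpa
lpa_v014	T	0.4958	-1.698549	lpa
lpa_v015	G	0.5738	-4.213958	lpa
lpa_v016	C	0.9265	2.979238	lpa
lpa_v017	A	0.4273	-3.175811	lpa
lpa_v018	C	0.7221	-6.116097	lpa
lpa_v019	C	0.2304	0.637114	lpa
lpa_v020	G	0.0977	-7.900525	lpa
lpa_v021	A	0.1581	3.045756	lpa
lpa_v022	T	0.4798	-2.228358	lpa
lpa_v023	T	0.1667	4.455728	lpa
lpa_v024	T	0.4959	0.708327	lpa
lpa_v025	C	0.2348	0.129439	lpa
lpa_v026	G	0.8737	-2.749538	lpa
lpa_v027	C	0.7179	-4.052355	lpa
lpa_v028	C	0.5193	-4.725503	lpa
lpa_v029	G	0.9458	-10.301551	lpa
lpa_v030	T	0.0625	-1.32214	lpa
lpa_v031	A	0.6841	3.772249	lpa
lpa_v032	G	0.8143	3.719068	lpa
lpa_v033	G	0.2355	-0.454202	lpa
lpa_v034	A	0.1541	2.226319	lpa
lpa_v035	C	0.7707	-8.063516	lpa
lpa_v036	T	0.7431	3.624249	lpa
lpa_v037	G	0.7978	0.538458	lpa
lpa_v038	A	0.6869	0.494285	lpa
lpa_v039	A	0.2924	0.471023	lpa
lpa_v040	T	0.8771	0.968926	lpa
lpa_v041	G	0.3429	0.50224	lpa
lpa_v042	G	0.9031	0.896742	lpa
lpa_v043	A	0.5409	9.355102	lpa
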