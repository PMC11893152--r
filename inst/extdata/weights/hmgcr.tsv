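variant_id	effect_allele	eaf	beta	trait
hmgcr_v001	A	0.4916	0.269846	hmgcr
hmgcr_v002	C	0.2112	0.06466	hmgcr
hmgcr_v003	C	0.2056	-0.273606	hmgcr
hmgcr_v004	G	0.9375	0.713516	hmgcr
hmgcr_v005	A	0.204	-0.704681	hmgcr
hmgcr_v006	G	0.8561	-0.394477	hmgcr
hmgcr_v007	A	0.8904	-1.06318	hmgcr
hmgcr_v008	G	0.7017	0.272917	hmgcr
hmgcr_v009	G	0.5562	0.726421	hmgcr
hmgcr_v010	A	0.6612	-0.478954	hmgcr
hmgcr_v011	T	0.0651	0.033758	hmgcr
hmgcr_v012	G	0.5761	0.569968	hmgcr
hmgcr_v013	G	0.9148	-0.53608	hmgcr
hmgcr_v014	T	0.7414	0.039703	hmgcr
hmgcr_v015	G	0.8677	0.372605	hmgcr
hmgcr_v016	A	0.7117	0.240378	hmgcr
hmgcr_v017	G	0.731	-0.384691	hmgcr
hmgcr_v018	G	0.7739	-0.586874	hmgcr
hmgcr_v019	T	0.7233	-0.700962	hmgcr
hmgcr_v020	T	0.8334	-0.253625	hmgcr
hmgcr_v021	A	0.6207	-0.57613	hmgcr
hmgcr_v022	C	0.474	0.23493	hmgcr
hmgcr_v023	A	0.7558	-0.414273	hmgcr
hmgcr_v024	C	0.6633	-0.771878	hmgcr
hmgcr_v025	G	0.1231	-0.410264	hmgcr
hmgcr_v026	A	0.6437	-0.826133	hmgcr
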