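variant_id	effect_allele	eaf	beta	trait
alcohol_v001	T	0.2488	0.091761	alcohol
alcohol_v002	C	0.1992	-0.183099	alcohol
alcohol_v003	C	0.435	0.330395	alcohol
alcohol_v004	C	0.421	0.074413	alcohol
alcohol_v005	T	0.2086	0.134561	alcohol
alcohol_v006	G	0.0749	0.228284	alcohol
alcohol_v007	A	0.2407	0.105034	alcohol
alcohol_v008	C	0.5698	0.168672	alcohol
alcohol_v009	A	0.2133	-0.258168	alcohol
alcohol_v010	A	0.3115	0.024139	alcohol
alcohol_v011	A	0.3649	0.4763	alcohol
alcohol_v012	A	0.5048	-0.117315	alcohol
alcohol_v013	A	0.3466	0.358608	alcohol
alcohol_v014	A	0.1987	-0.055974	alcohol
alcohol_v015	T	0.7946	-0.676059	alcohol
alcohol_v016	C	0.4249	-0.491848	alcohol
alcohol_v017	T	0.3204	-0.936171	alcohol
alcohol_v018	G	0.8205	0.738261	alcohol
alcohol_v019	G	0.5541	0.418973	alcohol
alcohol_v020	G	0.152	0.305509	alcohol
alcohol_v021	C	0.1193	0.343804	alcohol
alcohol_v022	A	0.8509	0.123388	alcohol
alcohol_v023	G	0.1508	-0.235191	alcohol
alcohol_v024	C	0.4964	-0.339578	alcohol
alcohol_v025	A	0.8682	-0.05127	alcohol
alcohol_v026	A	0.2468	-0.394008	alcohol
alcohol_v027	C	0.8511	0.096763	alcohol
alcohol_v028	C	0.4903	0.028322	alcohol
alcohol_v029	T	0.3548	-0.187024	alcohol
alcohol_v030	G	0.7433	0.080903	alcohol
alcohol_v031	G	0.2152	-0.302356	alcohol
alcohol_v032	G	0.7255	0.521031	alcohol
alcohol_v033	A	0.5456	-0.128863	alcohol
alcohol_v034	T	0.1881	-0.66701	alcohol
alcohol_v035	C	0.1299	-0.268589	alcohol
alcohol_v036	C	0.2284	-0.180051	alcohol
alcohol_v037	A	0.1197	0.480549	alcohol
alcohol_v038	A	0.7994	0.291332	alcohol
alcohol_v039	A	0.451	-0.170347	alcohol
alcohol_v040	C	0.0874	0.629944	alcohol
alcohol_v041	A	0.1052	0.46522	alcohol
alcohol_v042	C	0.1615	-0.297013	alcohol
alcohol_v043	C	0.4818	0.092263	alcohol
alcohol_v044	C	0.0827	0.134996	alcohol
alcohol_v045	C	0.8579	-0.292414	alcohol
alcohol_v046	G	0.5761	0.554126	alcohol
alcohol_v047	C	0.0815	0.092586	alcohol
alcohol_v048	A	0.9023	0.058158	alcohol
alcohol_v049	A	0.3175	-0.228094	alcohol
alcohol_v050	G	0.6288	-0.244147	alcohol
alcohol_v051	G	0.5512	-0.042378	alcohol
alcohol_v052	G	0.5232	-0.402833	alcohol
alcohol_v053	C	0.5141	0.150704	alcohol
alcohol_v054	C	0.7885	0.265255	alcohol
alcohol_v055	T	0.4362	-0.28966	alcohol
alcohol_v056	C	0.3978	-0.124385	alcohol
alcohol_v057	C	0.3618	0.003308	alcohol
alcohol_v058	G	0.2863	-0.025586	alcohol
alcohol_v059	G	0.3749	-0.304806	alcohol
alcohol_v060	G	0.9153	0.553754	alcohol
alcohol_v061	G	0.3678	0.088724	alcohol
alcohol_v062	G	0.8864	0.188911	alcohol
alcohol_v063	C	0.1555	0.538607	alcohol
alcohol_v064	G	0.6436	0.049787	alcohol
alcohol_v065	C	0.6254	0.638863	alcohol
alcohol_v066	C	0.4	0.006301	alcohol
alcohol_v067	A	0.645	-0.492425	alcohol
alcohol_v068	A	0.6277	-0.662063	alcohol
alcohol_v069	T	0.8676	-0.117238	alcohol
alcohol_v070	A	0.8002	-0.410723	alcohol
alcohol_v071	G	0.7314	0.086858	alcohol
alcohol_v072	A	0.3354	-5.8e-05	alcohol
alcohol_v073	A	0.7336	-0.355991	alcohol
alcohol_v074	A	0.3228	-0.05057	alcohol
alcohol_v075	T	0.5412	-0.249285	alcohol
alcohol_v076	G	0.7024	-0.471321	alcohol
alcohol_v077	T	0.522	-0.194595	alcohol
alcohol_v078	C	0.9364	-0.096142	alcohol
alcohol_v079	G	0.778	0.320098	alcohol
alcohol_v080	C	0.862	-0.464471	alcohol
alcohol_v081	A	0.3444	-0.053049	alcohol
alcohol_v082	A	0.2409	-0.344881	alcohol
alcohol_v083	C	0.4919	0.238896	alcohol
alcohol_v084	G	0.5288	-0.068495	alcohol
alcohol_v085	G	0.9052	-0.499755	alcohol
alcohol_v086	T	0.2688	-0.767142	alcohol
alcohol_v087	T	0.768	-0.049459	alcohol
alcohol_v088	C	0.3202	-0.070153	alcohol
alcohol_v089	T	0.7884	-0.114441	alcohol
alcohol_v090	G	0.7143	0.137469	alcohol
alcohol_v091	T	0.9262	0.426446	alcohol
alcohol_v092	A	0.4519	0.001316	alcohol
alcohol_v093	G	0.4633	-0.157213	alcohol
alcohol_v094	C	0.2531	-0.52186	alcohol
alcohol_v095	A	0.8371	0.155243	alcohol
alcohol_v096	G	0.3283	0.544014	alcohol
alcohol_v097	C	0.6809	0.131565	alcohol
alcohol_v098	A	0.7235	-0.072726	alcohol
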