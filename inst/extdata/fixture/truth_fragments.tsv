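read_id	gene_id	isoform
g001_f00001	g001	S
g001_f00002	g001	S
g001_f00003	g001	S
g001_f00004	g001	S
g001_f00005	g001	S
g001_f00006	g001	S
g001_f00007	g001	S
g001_f00008	g001	S
g001_f00009	g001	S
g001_f00010	g001	S
g001_f00011	g001	S
g001_f00012	g001	S
g001_f00013	g001	S
g001_f00014	g001	S
g001_f00015	g001	S
g001_f00016	g001	S
g001_f00017	g001	S
g001_f00018	g001	S
g001_f00019	g001	S
g001_f00020	g001	S
g001_f00021	g001	S
g001_f00022	g001	S
g001_f00023	g001	S
g001_f00024	g001	S
g001_f00025	g001	S
g001_f00026	g001	S
g001_f00027	g001	S
g001_f00028	g001	S
g001_f00029	g001	S
g001_f00030	g001	S
g001_f00031	g001	S
g001_f00032	g001	S
g001_f00033	g001	S
g001_f00034	g001	S
g001_f00035	g001	S
g001_f00036	g001	S
g001_f00037	g001	R
g001_f00038	g001	R
g001_f00039	g001	R
g001_f00040	g001	R
g001_f00041	g001	R
g001_f00042	g001	R
g001_f00043	g001	R
g001_f00044	g001	R
g001_f00045	g001	R
g001_f00046	g001	R
g001_f00047	g001	R
g001_f00048	g001	R
g001_f00049	g001	R
g001_f00050	g001	R
g001_f00051	g001	R
g001_f00052	g001	R
g001_f00053	g001	R
g001_f00054	g001	R
g001_f00055	g001	R
g001_f00056	g001	R
g001_f00057	g001	R
g001_f00058	g001	R
g001_f00059	g001	R
g001_f00060	g001	R
g001_f00061	g001	R
g001_f00062	g001	R
g001_f00063	g001	R
g001_f00064	g001	R
g001_f00065	g001	R
g001_f00066	g001	R
g001_f00067	g001	R
g001_f00068	g001	R
g001_f00069	g001	R
g001_f00070	g001	R
g001_f00071	g001	R
g001_f00072	g001	R
g001_f00073	g001	R
g001_f00074	g001	R
g001_f00075	g001	R
g001_f00076	g001	R
g001_f00077	g001	R
g001_f00078	g001	R
g001_f00079	g001	R
g001_f00080	g001	R
g001_f00081	g001	R
g001_f00082	g001	R
g001_f00083	g001	R
g001_f00084	g001	R
g001_f00085	g001	R
g001_f00086	g001	R
g001_f00087	g001	R
g001_f00088	g001	R
g001_f00089	g001	R
g001_f00090	g001	R
g001_f00091	g001	R
g001_f00092	g001	R
g001_f00093	g001	R
g001_f00094	g001	R
g001_f00095	g001	R
g001_f00096	g001	R
g001_f00097	g001	R
g001_f00098	g001	R
g001_f00099	g001	R
g001_f00100	g001	R
g001_f00101	g001	R
g001_f00102	g001	R
g001_f00103	g001	R
g001_f00104	g001	R
g001_f00105	g001	R
g001_f00106	g001	R
g001_f00107	g001	R
g001_f00108	g001	R
g001_f00109	g001	R
g001_f00110	g001	R
g001_f00111	g001	R
g001_f00112	g001	R
g001_f00113	g001	R
g001_f00114	g001	R
g001_f00115	g001	R
g001_f00116	g001	R
g001_f00117	g001	R
g001_f00118	g001	R
g001_f00119	g001	R
g001_f00120	g001	R
g001_f00121	g001	R
g001_f00122	g001	R
g001_f00123	g001	R
g001_f00124	g001	R
g001_f00125	g001	R
g001_f00126	g001	R
g001_f00127	g001	R
g001_f00128	g001	R
g001_f00129	g001	R
g001_f00130	g001	R
g001_f00131	g001	R
g001_f00132	g001	R
g001_f00133	g001	R
g001_f00134	g001	R
g001_f00135	g001	R
g001_f00136	g001	R
g001_f00137	g001	R
g001_f00138	g001	R
g001_f00139	g001	R
g001_f00140	g001	R
g001_f00141	g001	R
g001_f00142	g001	R
g001_f00143	g001	R
g001_f00144	g001	R
g001_f00145	g001	R
g001_f00146	g001	R
g001_f00147	g001	R
g001_f00148	g001	R
g001_f00149	g001	R
g001_f00150	g001	R
g001_f00151	g001	R
g001_f00152	g001	R
g001_f00153	g001	R
g001_f00154	g001	R
g001_f00155	g001	R
g001_f00156	g001	R
g001_f00157	g001	R
g001_f00158	g001	R
g001_f00159	g001	M
g002_f00001	g002	""
g002_f00002	g002	""
g002_f00003	g002	""
g002_f00004	g002	""
g002_f00005	g002	""
g002_f00006	g002	""
g002_f00007	g002	""
g002_f00008	g002	""
g002_f00009	g002	""
g002_f00010	g002	""
g002_f00011	g002	""
g002_f00012	g002	""
g002_f00013	g002	""
g002_f00014	g002	""
g002_f00015	g002	""
g002_f00016	g002	""
g002_f00017	g002	""
g002_f00018	g002	""
g002_f00019	g002	""
g002_f00020	g002	""
g002_f00021	g002	""
g002_f00022	g002	""
g002_f00023	g002	""
g002_f00024	g002	""
g002_f00025	g002	""
g002_f00026	g002	""
g002_f00027	g002	""
g002_f00028	g002	""
g002_f00029	g002	""
g002_f00030	g002	""
g002_f00031	g002	""
g002_f00032	g002	""
g003_f00001	g003	S
g003_f00002	g003	S
g003_f00003	g003	S
g003_f00004	g003	S
g003_f00005	g003	S
g003_f00006	g003	S
g003_f00007	g003	S
g003_f00008	g003	S
g003_f00009	g003	S
g003_f00010	g003	S
g003_f00011	g003	S
g003_f00012	g003	S
g003_f00013	g003	S
g003_f00014	g003	S
g003_f00015	g003	S
g003_f00016	g003	S
g003_f00017	g003	S
g003_f00018	g003	S
g003_f00019	g003	S
g003_f00020	g003	S
g003_f00021	g003	S
g003_f00022	g003	S
g003_f00023	g003	S
g003_f00024	g003	S
g003_f00025	g003	S
g003_f00026	g003	S
g003_f00027	g003	S
g003_f00028	g003	S
g003_f00029	g003	S
g003_f00030	g003	S
g003_f00031	g003	S
g003_f00032	g003	S
g003_f00033	g003	S
g003_f00034	g003	S
g003_f00035	g003	S
g003_f00036	g003	S
g003_f00037	g003	S
g003_f00038	g003	S
g003_f00039	g003	S
g003_f00040	g003	S
g003_f00041	g003	S
g003_f00042	g003	S
g003_f00043	g003	S
g003_f00044	g003	S
g003_f00045	g003	S
g003_f00046	g003	S
g003_f00047	g003	S
g003_f00048	g003	S
g003_f00049	g003	S
g003_f00050	g003	S
g003_f00051	g003	S
g003_f00052	g003	S
g003_f00053	g003	S
g003_f00054	g003	S
g003_f00055	g003	S
g003_f00056	g003	S
g003_f00057	g003	S
g003_f00058	g003	S
g003_f00059	g003	S
g003_f00060	g003	S
g003_f00061	g003	S
g003_f00062	g003	S
g003_f00063	g003	S
g003_f00064	g003	S
g003_f00065	g003	S
g003_f00066	g003	S
g003_f00067	g003	S
g003_f00068	g003	S
g003_f00069	g003	S
g003_f00070	g003	S
g003_f00071	g003	S
g003_f00072	g003	S
g003_f00073	g003	S
g003_f00074	g003	S
g003_f00075	g003	S
g003_f00076	g003	S
g003_f00077	g003	S
g003_f00078	g003	S
g003_f00079	g003	M
g003_f00080	g003	M
g003_f00081	g003	M
gNest_f00001	gNest	""
gNest_f00002	gNest	""
gNest_f00003	gNest	""
gNest_f00004	gNest	""
gNest_f00005	gNest	""
gNest_f00006	gNest	""
gNest_f00007	gNest	""
gNest_f00008	gNest	""
gNest_f00009	gNest	""
gNest_f00010	gNest	""
gNest_f00011	gNest	""
gNest_f00012	gNest	""
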