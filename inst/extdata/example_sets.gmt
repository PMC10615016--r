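androgen_response	synthetic androgen-response-like 97-gene set	gene00001	gene00002	gene00003	gene00004	gene00005	gene00006	gene00007	gene00008	gene00009	gene00010	gene00011	gene00012	gene00013	gene00014	gene00015	gene00016	gene00017	gene00018	gene00019	gene00020	gene00021	gene00022	gene00023	gene00024	gene00025	gene00026	gene00027	gene00028	gene00029	gene00030	gene00031	gene00032	gene00033	gene00034	gene00035	gene00036	gene00037	gene00038	gene00039	gene00040	gene00041	gene00042	gene00043	gene00044	gene00045	gene00046	gene00047	gene00048	gene00049	gene00050	gene00051	gene00052	gene00053	gene00054	gene00055	gene00056	gene00057	gene00058	gene00059	gene00060	gene00061	gene00062	gene00063	gene00064	gene00065	gene00066	gene00067	gene00068	gene00069	gene00070	gene00071	gene00072	gene00073	gene00074	gene00075	gene00076	gene00077	gene00078	gene00079	gene00080	gene00081	gene00082	gene00083	gene00084	gene00085	gene00086	gene00087	gene00088	gene00089	gene00090	gene00091	gene00092	gene00093	gene00094	gene00095	gene00096	gene00097
immune_response	synthetic immune-response-like 200-gene set	gene00098	gene00099	gene00100	gene00101	gene00102	gene00103	gene00104	gene00105	gene00106	gene00107	gene00108	gene00109	gene00110	gene00111	gene00112	gene00113	gene00114	gene00115	gene00116	gene00117	gene00118	gene00119	gene00120	gene00121	gene00122	gene00123	gene00124	gene00125	gene00126	gene00127	gene00128	gene00129	gene00130	gene00131	gene00132	gene00133	gene00134	gene00135	gene00136	gene00137	gene00138	gene00139	gene00140	gene00141	gene00142	gene00143	gene00144	gene00145	gene00146	gene00147	gene00148	gene00149	gene00150	gene00151	gene00152	gene00153	gene00154	gene00155	gene00156	gene00157	gene00158	gene00159	gene00160	gene00161	gene00162	gene00163	gene00164	gene00165	gene00166	gene00167	gene00168	gene00169	gene00170	gene00171	gene00172	gene00173	gene00174	gene00175	gene00176	gene00177	gene00178	gene00179	gene00180	gene00181	gene00182	gene00183	gene00184	gene00185	gene00186	gene00187	gene00188	gene00189	gene00190	gene00191	gene00192	gene00193	gene00194	gene00195	gene00196	gene00197	gene00198	gene00199	gene00200	gene00201	gene00202	gene00203	gene00204	gene00205	gene00206	gene00207	gene00208	gene00209	gene00210	gene00211	gene00212	gene00213	gene00214	gene00215	gene00216	gene00217	gene00218	gene00219	gene00220	gene00221	gene00222	gene00223	gene00224	gene00225	gene00226	gene00227	gene00228	gene00229	gene00230	gene00231	gene00232	gene00233	gene00234	gene00235	gene00236	gene00237	gene00238	gene00239	gene00240	gene00241	gene00242	gene00243	gene00244	gene00245	gene00246	gene00247	gene00248	gene00249	gene00250	gene00251	gene00252	gene00253	gene00254	gene00255	gene00256	gene00257	gene00258	gene00259	gene00260	gene00261	gene00262	gene00263	gene00264	gene00265	gene00266	gene00267	gene00268	gene00269	gene00270	gene00271	gene00272	gene00273	gene00274	gene00275	gene00276	gene00277	gene00278	gene00279	gene00280	gene00281	gene00282	gene00283	gene00284	gene00285	gene00286	gene00287	gene00288	gene00289	gene00290	gene00291	gene00292	gene00293	gene00294	gene00295	gene00296	gene00297
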