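g0001	brain
g0002	brain
g0004	brain
g0007	brain
g0008	brain
g0011	brain
g0013	brain
g0018	brain
g0019	brain
g0023	brain
g0027	brain
g0030	brain
g0031	brain
g0033	brain
g0035	brain
g0036	brain
g0037	brain
g0040	brain
g0041	brain
g0042	brain
g0046	brain
g0053	brain
g0058	brain
g0061	brain
g0064	brain
g0067	brain
g0072	brain
g0074	brain
g0081	brain
g0083	brain
g0086	brain
g0087	brain
g0090	brain
g0094	brain
g0098	brain
g0099	brain
g0111	brain
g0112	brain
g0114	brain
g0118	brain
g0120	brain
g0128	brain
g0129	brain
g0131	brain
g0133	brain
g0134	brain
g0140	brain
g0146	brain
g0150	brain
g0151	brain
g0154	brain
g0158	brain
g0161	brain
g0162	brain
g0164	brain
g0165	brain
g0166	brain
g0167	brain
g0168	brain
g0169	brain
g0171	brain
g0176	brain
g0177	brain
g0180	brain
g0181	brain
g0193	brain
g0194	brain
g0196	brain
g0201	brain
g0203	brain
g0204	brain
g0205	brain
g0209	brain
g0212	brain
g0217	brain
g0218	brain
g0224	brain
g0226	brain
g0227	brain
g0230	brain
g0233	brain
g0236	brain
g0238	brain
g0243	brain
g0244	brain
g0246	brain
g0253	brain
g0254	brain
g0260	brain
g0261	brain
g0262	brain
g0265	brain
g0268	brain
g0272	brain
g0273	brain
g0275	brain
g0276	brain
g0283	brain
g0291	brain
g0293	brain
g0296	brain
g0299	brain
g0001	generic
g0002	generic
g0003	generic
g0005	generic
g0006	generic
g0012	generic
g0013	generic
g0014	generic
g0017	generic
g0019	generic
g0020	generic
g0023	generic
g0025	generic
g0030	generic
g0031	generic
g0032	generic
g0033	generic
g0036	generic
g0038	generic
g0039	generic
g0040	generic
g0043	generic
g0045	generic
g0046	generic
g0047	generic
g0048	generic
g0049	generic
g0051	generic
g0053	generic
g0056	generic
g0058	generic
g0059	generic
g0061	generic
g0062	generic
g0063	generic
g0065	generic
g0070	generic
g0078	generic
g0079	generic
g0080	generic
g0085	generic
g0086	generic
g0087	generic
g0088	generic
g0091	generic
g0092	generic
g0094	generic
g0095	generic
g0096	generic
g0099	generic
g0101	generic
g0105	generic
g0109	generic
g0110	generic
g0112	generic
g0114	generic
g0117	generic
g0118	generic
g0119	generic
g0120	generic
g0122	generic
g0124	generic
g0125	generic
g0127	generic
g0128	generic
g0131	generic
g0134	generic
g0135	generic
g0136	generic
g0138	generic
g0140	generic
g0142	generic
g0143	generic
g0145	generic
g0146	generic
g0147	generic
g0148	generic
g0149	generic
g0155	generic
g0157	generic
g0158	generic
g0161	generic
g0162	generic
g0165	generic
g0166	generic
g0167	generic
g0168	generic
g0169	generic
g0173	generic
g0178	generic
g0179	generic
g0181	generic
g0182	generic
g0184	generic
g0185	generic
g0186	generic
g0187	generic
g0188	generic
g0189	generic
g0190	generic
g0191	generic
g0195	generic
g0201	generic
g0203	generic
g0204	generic
g0207	generic
g0208	generic
g0209	generic
g0210	generic
g0211	generic
g0212	generic
g0214	generic
g0215	generic
g0217	generic
g0219	generic
g0220	generic
g0223	generic
g0224	generic
g0228	generic
g0229	generic
g0230	generic
g0231	generic
g0233	generic
g0234	generic
g0236	generic
g0237	generic
g0238	generic
g0242	generic
g0243	generic
g0245	generic
g0247	generic
g0249	generic
g0251	generic
g0255	generic
g0256	generic
g0258	generic
g0261	generic
g0264	generic
g0267	generic
g0268	generic
g0269	generic
g0274	generic
g0275	generic
g0276	generic
g0279	generic
g0280	generic
g0281	generic
g0282	generic
g0287	generic
g0289	generic
g0290	generic
g0291	generic
g0293	generic
g0295	generic
g0298	generic
g0299	generic
g0300	generic
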