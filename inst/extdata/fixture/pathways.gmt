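P1	synthetic pathway 1	g0008	g0019	g0027	g0053	g0067	g0074	g0094	g0098	g0099	g0120	g0151	g0158	g0166	g0167	g0176	g0201	g0203	g0209	g0217	g0226	g0230	g0236	g0246	g0253	g0254	g0265	g0272	g0273	g0276	g0296
P2	synthetic pathway 2	g0006	g0012	g0036	g0059	g0061	g0077	g0102	g0106	g0107	g0108	g0118	g0129	g0165	g0178	g0179	g0184	g0188	g0193	g0232	g0238	g0244	g0245	g0257	g0266	g0275	g0280	g0284	g0286	g0292	g0293
P3	synthetic pathway 3	g0003	g0007	g0014	g0025	g0038	g0045	g0049	g0050	g0056	g0057	g0083	g0084	g0097	g0121	g0126	g0147	g0150	g0154	g0171	g0174	g0175	g0183	g0202	g0223	g0229	g0239	g0258	g0268	g0283	g0288
P4	synthetic pathway 4	g0016	g0060	g0071	g0072	g0085	g0091	g0093	g0095	g0101	g0119	g0128	g0146	g0155	g0170	g0185	g0196	g0198	g0204	g0208	g0210	g0215	g0222	g0235	g0249	g0255	g0281	g0287	g0290	g0298	g0300
P5	synthetic pathway 5	g0002	g0033	g0043	g0047	g0051	g0062	g0064	g0073	g0087	g0092	g0109	g0125	g0134	g0139	g0140	g0145	g0152	g0159	g0161	g0173	g0187	g0197	g0205	g0214	g0218	g0221	g0224	g0251	g0274	g0297
P6	synthetic pathway 6	g0010	g0011	g0013	g0026	g0028	g0035	g0042	g0046	g0069	g0081	g0082	g0103	g0113	g0124	g0131	g0136	g0153	g0172	g0182	g0199	g0213	g0225	g0227	g0237	g0250	g0259	g0263	g0267	g0271	g0295
P7	synthetic pathway 7	g0001	g0009	g0023	g0037	g0040	g0088	g0089	g0104	g0105	g0112	g0115	g0116	g0130	g0137	g0181	g0186	g0211	g0212	g0216	g0228	g0248	g0256	g0260	g0261	g0262	g0278	g0279	g0285	g0289	g0294
P8	synthetic pathway 8	g0018	g0020	g0022	g0031	g0044	g0052	g0054	g0063	g0066	g0068	g0075	g0078	g0096	g0100	g0110	g0122	g0132	g0143	g0144	g0162	g0163	g0168	g0169	g0180	g0191	g0192	g0240	g0277	g0282	g0291
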