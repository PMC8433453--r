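patient_id	blood	tumor
pt_328	5/5	5/5
pt_197	4/5	4/5
pt_118	4/4	4/4
pt_145	4/4	4/4
pt_260	4/5	4/5
pt_326	5/5	5/5
pt_093	4/4	4/4
pt_034	4/4	4/4
pt_283	4/5	4/5
pt_092	4/4	4/4
pt_271	4/5	4/5
pt_280	4/5	4/5
pt_085	4/4	4/4
pt_241	4/5	4/5
pt_033	4/4	4/4
pt_204	4/5	4/5
pt_008	4/4	4/4
pt_262	4/5	4/5
pt_265	4/5	4/5
pt_164	4/5	4/4
pt_026	4/4	4/4
pt_303	5/5	5/5
pt_177	4/5	5/5
pt_003	4/4	4/4
pt_024	4/4	4/4
pt_322	5/5	5/5
pt_005	4/4	4/4
pt_080	4/4	4/4
pt_069	4/4	4/4
pt_237	4/5	4/5
pt_062	4/4	4/4
pt_202	4/5	4/5
pt_213	4/5	4/5
pt_148	4/4	4/4
pt_255	4/5	4/5
pt_236	4/5	4/5
pt_051	4/4	4/4
pt_142	4/4	4/4
pt_029	4/4	4/4
pt_229	4/5	4/5
pt_296	5/5	5/5
pt_091	4/4	4/4
pt_074	4/4	4/4
pt_324	5/5	5/5
pt_055	4/4	4/4
pt_123	4/4	4/4
pt_036	4/4	4/4
pt_263	4/5	4/5
pt_016	4/4	4/4
pt_178	4/5	5/5
pt_327	5/5	5/5
pt_190	4/5	5/5
pt_259	4/5	4/5
pt_198	4/5	4/5
pt_175	4/5	5/5
pt_019	4/4	4/4
pt_316	5/5	5/5
pt_307	5/5	5/5
pt_284	4/5	4/5
pt_167	4/5	4/4
pt_063	4/4	4/4
pt_286	4/5	4/5
pt_293	4/5	4/5
pt_215	4/5	4/5
pt_078	4/4	4/4
pt_059	4/4	4/4
pt_096	4/4	4/4
pt_050	4/4	4/4
pt_023	4/4	4/4
pt_159	4/5	4/4
pt_073	4/4	4/4
pt_270	4/5	4/5
pt_166	4/5	4/4
pt_107	4/4	4/4
pt_088	4/4	4/4
pt_079	4/4	4/4
pt_045	4/4	4/4
pt_052	4/4	4/4
pt_153	4/4	4/4
pt_043	4/4	4/4
pt_087	4/4	4/4
pt_127	4/4	4/4
pt_173	4/5	5/5
pt_094	4/4	4/4
pt_200	4/5	4/5
pt_149	4/4	4/4
pt_227	4/5	4/5
pt_195	4/5	4/5
pt_201	4/5	4/5
pt_151	4/4	4/4
pt_154	4/4	4/4
pt_141	4/4	4/4
pt_310	5/5	5/5
pt_187	4/5	5/5
pt_135	4/4	4/4
pt_170	4/5	5/5
pt_252	4/5	4/5
pt_139	4/4	4/4
pt_083	4/4	4/4
pt_183	4/5	5/5
pt_318	5/5	5/5
pt_205	4/5	4/5
pt_174	4/5	5/5
pt_044	4/4	4/4
pt_239	4/5	4/5
pt_163	4/5	4/4
pt_249	4/5	4/5
pt_179	4/5	5/5
pt_291	4/5	4/5
pt_022	4/4	4/4
pt_193	4/5	4/5
pt_039	4/4	4/4
pt_002	4/4	4/4
pt_132	4/4	4/4
pt_049	4/4	4/4
pt_056	4/4	4/4
pt_025	4/4	4/4
pt_161	4/5	4/4
pt_221	4/5	4/5
pt_196	4/5	4/5
pt_302	5/5	5/5
pt_090	4/4	4/4
pt_098	4/4	4/4
pt_323	5/5	5/5
pt_117	4/4	4/4
pt_143	4/4	4/4
pt_233	4/5	4/5
pt_245	4/5	4/5
pt_308	5/5	5/5
pt_157	4/5	4/4
pt_102	4/4	4/4
pt_035	4/4	4/4
pt_100	4/4	4/4
pt_274	4/5	4/5
pt_114	4/4	4/4
pt_298	5/5	5/5
pt_285	4/5	4/5
pt_264	4/5	4/5
pt_281	4/5	4/5
pt_133	4/4	4/4
pt_256	4/5	4/5
pt_191	4/5	5/5
pt_001	4/4	4/4
pt_242	4/5	4/5
pt_048	4/4	4/4
pt_257	4/5	4/5
pt_329	5/5	5/5
pt_097	4/4	4/4
pt_207	4/5	4/5
pt_134	4/4	4/4
pt_131	4/4	4/4
pt_223	4/5	4/5
pt_150	4/4	4/4
pt_017	4/4	4/4
pt_300	5/5	5/5
pt_216	4/5	4/5
pt_279	4/5	4/5
pt_188	4/5	5/5
pt_189	4/5	5/5
pt_103	4/4	4/4
pt_064	4/4	4/4
pt_325	5/5	5/5
pt_007	4/4	4/4
pt_269	4/5	4/5
pt_309	5/5	5/5
pt_038	4/4	4/4
pt_046	4/4	4/4
pt_299	5/5	5/5
pt_152	4/4	4/4
pt_158	4/5	4/4
pt_192	4/5	4/5
pt_240	4/5	4/5
pt_129	4/4	4/4
pt_311	5/5	5/5
pt_068	4/4	4/4
pt_018	4/4	4/4
pt_248	4/5	4/5
pt_304	5/5	5/5
pt_297	5/5	5/5
pt_155	4/4	4/4
pt_109	4/4	4/4
pt_160	4/5	4/4
pt_176	4/5	5/5
pt_075	4/4	4/4
pt_292	4/5	4/5
pt_165	4/5	4/4
pt_211	4/5	4/5
pt_146	4/4	4/4
pt_272	4/5	4/5
pt_267	4/5	4/5
pt_113	4/4	4/4
pt_012	4/4	4/4
pt_306	5/5	5/5
pt_004	4/4	4/4
pt_320	5/5	5/5
pt_289	4/5	4/5
pt_119	4/4	4/4
pt_040	4/4	4/4
pt_317	5/5	5/5
pt_312	5/5	5/5
pt_182	4/5	5/5
pt_053	4/4	4/4
pt_234	4/5	4/5
pt_042	4/4	4/4
pt_172	4/5	5/5
pt_028	4/4	4/4
pt_009	4/4	4/4
pt_136	4/4	4/4
pt_203	4/5	4/5
pt_314	5/5	5/5
pt_054	4/4	4/4
pt_010	4/4	4/4
pt_258	4/5	4/5
pt_070	4/4	4/4
pt_031	4/4	4/4
pt_290	4/5	4/5
pt_089	4/4	4/4
pt_121	4/4	4/4
pt_066	4/4	4/4
pt_081	4/4	4/4
pt_130	4/4	4/4
pt_006	4/4	4/4
pt_232	4/5	4/5
pt_061	4/4	4/4
pt_138	4/4	4/4
pt_077	4/4	4/4
pt_128	4/4	4/4
pt_116	4/4	4/4
pt_250	4/5	4/5
pt_110	4/4	4/4
pt_027	4/4	4/4
pt_273	4/5	4/5
pt_112	4/4	4/4
pt_222	4/5	4/5
pt_295	5/5	5/5
pt_125	4/4	4/4
pt_140	4/4	4/4
pt_238	4/5	4/5
pt_305	5/5	5/5
pt_057	4/4	4/4
pt_218	4/5	4/5
pt_076	4/4	4/4
pt_231	4/5	4/5
pt_180	4/5	5/5
pt_168	4/5	5/5
pt_275	4/5	4/5
pt_014	4/4	4/4
pt_235	4/5	4/5
pt_217	4/5	4/5
pt_156	4/5	4/4
pt_065	4/4	4/4
pt_086	4/4	4/4
pt_210	4/5	4/5
pt_220	4/5	4/5
pt_268	4/5	4/5
pt_104	4/4	4/4
pt_101	4/4	4/4
pt_185	4/5	5/5
pt_251	4/5	4/5
pt_021	4/4	4/4
pt_209	4/5	4/5
pt_194	4/5	4/5
pt_111	4/4	4/4
pt_224	4/5	4/5
pt_099	4/4	4/4
pt_313	5/5	5/5
pt_277	4/5	4/5
pt_162	4/5	4/4
pt_225	4/5	4/5
pt_084	4/4	4/4
pt_144	4/4	4/4
pt_095	4/4	4/4
pt_013	4/4	4/4
pt_276	4/5	4/5
pt_294	5/5	5/5
pt_071	4/4	4/4
pt_171	4/5	5/5
pt_105	4/4	4/4
pt_181	4/5	5/5
pt_186	4/5	5/5
pt_122	4/4	4/4
pt_106	4/4	4/4
pt_214	4/5	4/5
pt_321	5/5	5/5
pt_288	4/5	4/5
pt_208	4/5	4/5
pt_287	4/5	4/5
pt_108	4/4	4/4
pt_011	4/4	4/4
pt_115	4/4	4/4
pt_278	4/5	4/5
pt_032	4/4	4/4
pt_184	4/5	5/5
pt_246	4/5	4/5
pt_082	4/4	4/4
pt_206	4/5	4/5
pt_226	4/5	4/5
pt_037	4/4	4/4
pt_319	5/5	5/5
pt_261	4/5	4/5
pt_126	4/4	4/4
pt_228	4/5	4/5
pt_020	4/4	4/4
pt_247	4/5	4/5
pt_282	4/5	4/5
pt_301	5/5	5/5
pt_253	4/5	4/5
pt_060	4/4	4/4
pt_041	4/4	4/4
pt_254	4/5	4/5
pt_030	4/4	4/4
pt_124	4/4	4/4
pt_058	4/4	4/4
pt_219	4/5	4/5
pt_047	4/4	4/4
pt_243	4/5	4/5
pt_315	5/5	5/5
pt_120	4/4	4/4
pt_147	4/4	4/4
pt_015	4/4	4/4
pt_212	4/5	4/5
pt_199	4/5	4/5
pt_072	4/4	4/4
pt_244	4/5	4/5
pt_230	4/5	4/5
pt_137	4/4	4/4
pt_067	4/4	4/4
pt_266	4/5	4/5
pt_169	4/5	5/5
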