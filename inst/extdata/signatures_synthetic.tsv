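Type	SBS1	SBS2	SBS5	SBS13	SBS40
A[C>A]A	0.00111104	0.00083101	0.00651818	0.00043041	0.02090239
A[C>A]C	0.00110904	0.00069517	0.00539317	0.00057442	0.0282547
A[C>A]G	0.00099762	0.00063268	0.01374487	0.00054931	0.02903445
A[C>A]T	0.00106819	0.000603	0.00686417	0.0010716	0.02556282
C[C>A]A	0.00151217	0.00051336	0.00795616	0.00066263	0.02371961
C[C>A]C	0.00145225	0.00089095	0.00831704	0.00069278	0.02810261
C[C>A]G	0.00148744	0.00056632	0.01203589	0.00070386	0.02891126
C[C>A]T	0.00140719	0.0007909	0.00776258	0.00074846	0.01957805
G[C>A]A	0.00152573	0.00064461	0.00445921	0.00064212	0.02452903
G[C>A]C	0.00144549	0.00103105	0.00655491	0.00081417	0.01632141
G[C>A]G	0.00105139	0.00065014	0.0038225	0.00049776	0.032768
G[C>A]T	0.00120749	0.00054963	0.00670505	0.00060418	0.02684861
T[C>A]A	0.00232078	0.00059356	0.00597016	0.00734424	0.04230391
T[C>A]C	0.00137637	0.00068276	0.00745364	0.00911726	0.02438167
T[C>A]G	0.00149771	0.00047856	0.01248892	0.01310566	0.0343428
T[C>A]T	0.00140984	0.00053542	0.00606451	0.00859103	0.0260679
A[C>G]A	0.00141526	0.00071348	0.00695238	0.00066973	0.00680806
A[C>G]C	0.00138072	0.00093846	0.00709631	0.00060934	0.00906445
A[C>G]G	0.00144602	0.00091294	0.00381739	0.00052124	0.00665929
A[C>G]T	0.00071863	0.00057171	0.00701286	0.0008086	0.00581378
C[C>G]A	0.00124687	0.00102385	0.00724506	0.00048097	0.0092775
C[C>G]C	0.00117975	0.00062788	0.00545683	0.00077073	0.00641149
C[C>G]G	0.00154035	0.00052357	0.00785317	0.00046596	0.00705383
C[C>G]T	0.00125371	0.00081544	0.00944386	0.00098868	0.00431189
G[C>G]A	0.00165169	0.00085714	0.00725709	0.00043327	0.00534661
G[C>G]C	0.00093605	0.00051481	0.00674894	0.00080875	0.00504422
G[C>G]G	0.00103797	0.00071038	0.00784387	0.00055292	0.00528778
G[C>G]T	0.00134229	0.00068694	0.00685176	0.00082728	0.00738659
T[C>G]A	0.00110045	0.00079499	0.0086742	0.39419154	0.00559444
T[C>G]C	0.00093066	0.00068525	0.00538559	0.12207859	0.00653415
T[C>G]G	0.00114313	0.00095125	0.00542922	0.04954143	0.00458372
T[C>G]T	0.00142355	0.00043684	0.00537886	0.33883018	0.00402239
A[C>T]A	0.00185523	0.0009203	0.02087137	0.00093841	0.00250158
A[C>T]C	0.00097018	0.00080613	0.01756718	0.00049923	0.00312909
A[C>T]G	0.28681908	0.00076345	0.01286595	0.00049285	0.00292651
A[C>T]T	0.00127729	0.00089421	0.01968613	0.00058759	0.00320958
C[C>T]A	0.00130645	0.00071095	0.01408937	0.00056024	0.00438067
C[C>T]C	0.00101745	0.00086869	0.02468735	0.00067895	0.00318199
C[C>T]G	0.15232748	0.00085832	0.01160617	0.000688	0.0027545
C[C>T]T	0.00201152	0.00049001	0.0142683	0.00080678	0.00210329
G[C>T]A	0.00111738	0.00047943	0.0124483	0.00071475	0.00332667
G[C>T]C	0.00099025	0.00086208	0.00911282	0.00072261	0.00221992
G[C>T]G	0.17505815	0.0004778	0.01898544	0.00066998	0.00479267
G[C>T]T	0.00112445	0.00081537	0.0161903	0.00071264	0.00188949
T[C>T]A	0.00186692	0.3537967	0.01599203	0.00063486	0.00288007
T[C>T]C	0.00120037	0.13742274	0.02044364	0.00060649	0.00325451
T[C>T]G	0.26079533	0.04930413	0.0163688	0.00055918	0.00231312
T[C>T]T	0.00098541	0.39166591	0.0167184	0.00047521	0.00404737
A[T>A]A	0.00122493	0.00072217	0.00970659	0.00051293	0.02335323
A[T>A]C	0.0008863	0.0007855	0.00779336	0.00054776	0.02299515
A[T>A]G	0.00123495	0.00064461	0.00670615	0.00042159	0.01306191
A[T>A]T	0.00185168	0.0006462	0.00588915	0.00055963	0.01631278
C[T>A]A	0.0010771	0.00077479	0.00524163	0.00064311	0.01251054
C[T>A]C	0.00166103	0.00077448	0.00570466	0.00047573	0.00872192
C[T>A]G	0.00113973	0.00095793	0.01105894	0.00062318	0.01592535
C[T>A]T	0.00171743	0.00070694	0.01028817	0.00056848	0.0130934
G[T>A]A	0.00115142	0.00065264	0.00645467	0.00051932	0.02426977
G[T>A]C	0.00135624	0.00084723	0.00714818	0.00078762	0.0129111
G[T>A]G	0.00120569	0.00085617	0.00942515	0.00067602	0.01343777
G[T>A]T	0.00133401	0.00080454	0.00671284	0.00080577	0.01628957
T[T>A]A	0.00122347	0.00089273	0.00648997	0.00064724	0.01833219
T[T>A]C	0.00122353	0.00071551	0.00510093	0.00114155	0.01954195
T[T>A]G	0.00121781	0.00074594	0.00962367	0.00074604	0.01123819
T[T>A]T	0.00201495	0.00074545	0.0063763	0.00073329	0.01334225
A[T>C]A	0.00187231	0.00101911	0.02051446	0.00031737	0.00353001
A[T>C]C	0.00124764	0.0007248	0.02192591	0.00078802	0.0041772
A[T>C]G	0.0015913	0.00116484	0.01879453	0.00039654	0.00339845
A[T>C]T	0.00149868	0.00053051	0.00974803	0.00042455	0.00301877
C[T>C]A	0.00113628	0.00094542	0.01355248	0.00069171	0.00272152
C[T>C]C	0.00116823	0.00069345	0.01121138	0.00065678	0.0043652
C[T>C]G	0.0015122	0.00079791	0.01413134	0.00041797	0.00386203
C[T>C]T	0.00192559	0.00066044	0.01972209	0.00073171	0.00296822
G[T>C]A	0.00133833	0.00039712	0.01718066	0.00066659	0.0032771
G[T>C]C	0.00111925	0.00089773	0.01865498	0.00079256	0.00269418
G[T>C]G	0.00141057	0.00079756	0.01337555	0.00072664	0.00509709
G[T>C]T	0.00161829	0.00042341	0.01842463	0.0006457	0.00382561
T[T>C]A	0.00143186	0.00089488	0.01748447	0.0006065	0.00512208
T[T>C]C	0.00124696	0.00057461	0.01609807	0.00084562	0.00369836
T[T>C]G	0.0018056	0.00116774	0.01662362	0.00087452	0.0024014
T[T>C]T	0.00121525	0.00060936	0.01969539	0.00063727	0.00449628
A[T>G]A	0.00171539	0.00061086	0.00958011	0.00041891	0.00376796
A[T>G]C	0.00076449	0.00074214	0.00587377	0.00046851	0.00332849
A[T>G]G	0.00151404	0.00067345	0.00688458	0.00071854	0.00608723
A[T>G]T	0.00147104	0.00068546	0.00710446	0.00053682	0.0056528
C[T>G]A	0.00125712	0.00065559	0.00631438	0.0008027	0.00696878
C[T>G]C	0.00128432	0.00087779	0.00536975	0.00055857	0.00419225
C[T>G]G	0.00164661	0.00092962	0.00586488	0.00056953	0.00932289
C[T>G]T	0.00167569	0.00053034	0.00641585	0.00059332	0.00635351
G[T>G]A	0.00124337	0.00081177	0.00706065	0.00075133	0.01102808
G[T>G]C	0.00120346	0.00055464	0.01049297	0.00070987	0.00646105
G[T>G]G	0.00131267	0.00094809	0.00426382	0.00064117	0.00758467
G[T>G]T	0.00171206	0.00060539	0.00681226	0.00087765	0.01032857
T[T>G]A	0.00120664	0.00075241	0.00991696	0.00089902	0.00607176
T[T>G]C	0.00199026	0.00089698	0.00984047	0.00078036	0.00652629
T[T>G]G	0.0015279	0.00069024	0.01168672	0.00038096	0.00532063
T[T>G]T	0.00136655	0.00087324	0.00720052	0.00058656	0.00727403
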