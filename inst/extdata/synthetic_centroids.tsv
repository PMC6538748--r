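gene_id	Basal	Her2	LumA	LumB	Normal
G001	-0.871824597	-0.118156134	-0.96260209	-0.374713975	-0.738872465
G002	-0.871824597	-1.71194632	-0.96260209	-0.374713975	-0.254659022
G003	0.321380223	1.07504869	-2.15580691	-1.5679188	-0.241163655
G004	0.0020181956	-0.0441016596	-2.14747367	-0.67093187	-1.60293265
G005	-0.328835801	0.424832662	-1.50559089	-0.917702771	-0.176142053
G006	-0.871824597	0.650418779	-0.96260209	-0.374713975	-0.0577952638
G007	-1.58821001	-0.834541549	-0.246216675	0.34167144	-0.0502046317
G008	0.283865709	-0.0202162772	-2.52963979	-0.7664734	-2.0806403
G009	-1.56923494	-0.815566476	-0.265191747	0.322696368	-0.052102139
G010	-0.871824597	-0.118156134	-0.96260209	-0.374713975	-1.09732784
G011	-0.871824597	-0.118156134	-0.96260209	-0.374713975	-0.528150964
G012	-0.871824597	-0.118156134	-0.96260209	-0.374713975	0.578548798
G013	0.142583111	0.896251575	-1.9770098	-1.38912168	-0.223283944
G014	-1.46367785	-0.168313189	-0.160089203	-0.174085753	0.881297935
G015	0.209779405	0.963447869	-2.04420609	-1.45631798	-0.230003573
G016	-0.871824597	0.671330116	-0.96260209	-0.374713975	-0.0560526524
G017	-1.885478	-0.204058964	0.4118432	-0.0311026523	1.59621344
G018	0.273807281	1.02747574	-2.10823397	-1.52034585	-0.236406361
G019	-2.14764796	-1.3939795	0.313221273	0.901109388	0.00573916306
G020	-1.93547144	-1.18180298	0.101044752	0.688932867	-0.015478489
G021	-0.00605458681	-0.0447857938	-2.13652753	-0.668195334	-1.58924997
G022	-0.871824597	-0.826132753	-0.96260209	-0.374713975	-0.180841225
G023	-0.286212532	0.467455931	-1.54821415	-0.96032604	-0.18040438
G024	-1.67704297	-0.923374503	-0.15738372	0.430504395	-0.0413213363
G025	-0.871824597	-1.51906795	-0.96260209	-0.374713975	-0.238585825
G026	-0.871824597	-0.118156134	-0.96260209	-0.374713975	-0.52203429
G027	-0.871824597	-0.118156134	-0.96260209	-0.374713975	0.445012792
G028	0.56120953	1.31487799	-2.39563622	-1.8077481	-0.265146586
G029	0.553820151	1.30748861	-2.38824684	-1.80035872	-0.264407648
G030	-0.871824597	-1.59906929	-0.96260209	-0.374713975	-0.245252603
G031	0.111200343	-0.0348489353	-2.29551726	-0.707942768	-1.78798714
G032	-1.88688793	-1.13321946	0.0524612401	0.640349355	-0.0203368402
G033	-2.33971468	-0.242553598	1.02775734	0.122875884	2.36610612
G034	-1.99098384	-1.23731537	0.15655715	0.744445265	-0.0099272492
G035	0.457144909	-0.00553159916	-2.76459464	-0.825212112	-2.37433386
G036	-0.871824597	-0.118156134	-0.96260209	-0.374713975	0.451882985
G037	-1.71737402	-0.189812865	0.183905608	-0.0880870502	1.31129145
G038	-1.92077973	-0.207050636	0.459709956	-0.0191359632	1.65604688
G039	0.570631095	1.32429956	-2.40505778	-1.81716967	-0.266088742
G040	-0.871824597	-1.87328575	-0.96260209	-0.374713975	-0.268103975
G041	0.368030682	1.12169915	-2.20245737	-1.61456925	-0.245828701
G042	-0.871824597	-1.59805122	-0.96260209	-0.374713975	-0.245167764
G043	-0.871824597	-0.118156134	-0.96260209	-0.374713975	-0.950452205
G044	-0.279142497	-0.067928837	-1.76623884	-0.575623161	-1.12638911
G045	-2.18037079	-0.229049879	0.811697834	0.0688610064	2.09603173
G046	-2.20862616	-1.45495769	0.37419947	0.962087585	0.0118369827
G047	-2.12334716	-1.3696787	0.288920473	0.876808588	0.00330908307
G048	-1.99604785	-0.213429291	0.561768426	0.00637865439	1.78361997
G049	-1.90761459	-1.15394613	0.0731879041	0.661076019	-0.0182641738
MKI67	0.544175403	0.00184386639	-2.88260209	-0.854713975	-2.52184317
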