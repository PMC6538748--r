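sample_id	er_ihc	pr_ihc	her2_ihc	her2_fish	ki67_pct
S0001	80	80	0	NA	
S0002	0	0	3+	NA	42.2
S0003	0	0	0	NA	6.3
S0004	80	80	0	NA	
S0005	80	80	0	NA	40.7
S0006	80	80	0	NA	38.5
S0007	0	0	0	NA	40
S0008	80	80	0	NA	6.9
S0009	80	80	0	NA	40.2
S0010	0	0	0	NA	39.1
S0011	80	80	3+	NA	41.5
S0012	0	0	0	NA	39
S0013	0	0	3+	NA	40.9
S0014	0	0	0	NA	5.4
S0015	80	80	0	NA	37.6
S0016	0	0	3+	NA	40.3
S0017	0	0	3+	NA	40.2
S0018	80	80	0	NA	4.7
S0019	80	80	3+	NA	41.9
S0020	80	80	3+	NA	39.4
S0021	80	80	0	NA	
S0022	0	0	0	NA	5.9
S0023	0	0	3+	NA	40.6
S0024	0	0	3+	NA	42
S0025	80	80	0	NA	4.2
S0026	0	0	0	NA	39.1
S0027	80	80	0	NA	7.6
S0028	80	80	0	NA	
S0029	80	80	0	NA	37.2
S0030	80	80	0	NA	
S0031	0	0	0	NA	38.5
S0032	0	0	0	NA	42.9
S0033	80	80	0	NA	7.6
S0034	0	0	0	NA	41.8
S0035	80	80	0	NA	3.1
S0036	0	80	0	NA	
S0037	80	80	0	NA	6.8
S0038	80	80	0	NA	2.1
S0039	0	80	0	NA	
S0040	80	80	3+	NA	39.1
S0041	0	0	0	NA	3.2
S0042	80	80	0	NA	39.2
S0043	80	80	0	NA	5.6
S0044	0	0	3+	NA	42.6
S0045	80	80	0	NA	42.6
S0046	0	0	3+	NA	40.9
S0047	80	80	0	NA	
S0048	80	80	3+	NA	37.2
S0049	0	0	3+	NA	41.7
S0050	0	0	3+	NA	40.6
S0051	80	80	0	NA	2.1
S0052	80	80	0	NA	3
S0053	80	80	0	NA	7.9
S0054	0	0	0	NA	37.3
S0055	80	80	0	NA	2.2
S0056	0	0	0	NA	41.9
S0057	0	0	0	NA	39.2
S0058	80	80	0	NA	6.4
S0059	80	80	0	NA	2.7
S0060	80	80	3+	NA	39.1
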