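gene	block
SYN0001	1
SYN0002	1
SYN0003	1
SYN0004	1
SYN0005	1
SYN0006	1
SYN0007	1
SYN0008	1
SYN0009	1
SYN0010	1
SYN0011	1
SYN0012	1
SYN0013	1
SYN0014	1
SYN0015	1
SYN0016	1
SYN0017	1
SYN0018	1
SYN0019	1
SYN0020	1
SYN0021	2
SYN0022	2
SYN0023	2
SYN0024	2
SYN0025	2
SYN0026	2
SYN0027	2
SYN0028	2
SYN0029	2
SYN0030	2
SYN0031	2
SYN0032	2
SYN0033	2
SYN0034	2
SYN0035	2
SYN0036	2
SYN0037	2
SYN0038	2
SYN0039	2
SYN0040	2
SYN0041	3
SYN0042	3
SYN0043	3
SYN0044	3
SYN0045	3
SYN0046	3
SYN0047	3
SYN0048	3
SYN0049	3
SYN0050	3
SYN0051	3
SYN0052	3
SYN0053	3
SYN0054	3
SYN0055	3
SYN0056	3
SYN0057	3
SYN0058	3
SYN0059	3
SYN0060	3
SYN0061	4
SYN0062	4
SYN0063	4
SYN0064	4
SYN0065	4
SYN0066	4
SYN0067	4
SYN0068	4
SYN0069	4
SYN0070	4
SYN0071	4
SYN0072	4
SYN0073	4
SYN0074	4
SYN0075	4
SYN0076	4
SYN0077	4
SYN0078	4
SYN0079	4
SYN0080	4
SYN0081	5
SYN0082	5
SYN0083	5
SYN0084	5
SYN0085	5
SYN0086	5
SYN0087	5
SYN0088	5
SYN0089	5
SYN0090	5
SYN0091	5
SYN0092	5
SYN0093	5
SYN0094	5
SYN0095	5
SYN0096	5
SYN0097	5
SYN0098	5
SYN0099	5
SYN0100	5
SYN0101	6
SYN0102	6
SYN0103	6
SYN0104	6
SYN0105	6
SYN0106	6
SYN0107	6
SYN0108	6
SYN0109	6
SYN0110	6
SYN0111	6
SYN0112	6
SYN0113	6
SYN0114	6
SYN0115	6
SYN0116	6
SYN0117	6
SYN0118	6
SYN0119	6
SYN0120	6
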