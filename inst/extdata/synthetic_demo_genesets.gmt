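BLOCK_PROCESS_1	synthetic gene set (BLOCK_PROCESS_1)	SYN0002	SYN0003	SYN0005	SYN0006	SYN0007	SYN0008	SYN0009	SYN0010	SYN0011	SYN0012	SYN0014	SYN0015	SYN0016	SYN0017	SYN0018	SYN0020
BLOCK_PROCESS_2	synthetic gene set (BLOCK_PROCESS_2)	SYN0021	SYN0022	SYN0023	SYN0024	SYN0025	SYN0026	SYN0027	SYN0028	SYN0029	SYN0030	SYN0032	SYN0033	SYN0034	SYN0036	SYN0038	SYN0040
BLOCK_PROCESS_3	synthetic gene set (BLOCK_PROCESS_3)	SYN0041	SYN0042	SYN0045	SYN0048	SYN0049	SYN0050	SYN0051	SYN0052	SYN0053	SYN0054	SYN0055	SYN0056	SYN0057	SYN0058	SYN0059	SYN0060
BLOCK_PROCESS_4	synthetic gene set (BLOCK_PROCESS_4)	SYN0061	SYN0062	SYN0063	SYN0064	SYN0065	SYN0067	SYN0068	SYN0069	SYN0072	SYN0073	SYN0074	SYN0075	SYN0076	SYN0077	SYN0078	SYN0079
BLOCK_PROCESS_5	synthetic gene set (BLOCK_PROCESS_5)	SYN0082	SYN0083	SYN0085	SYN0086	SYN0087	SYN0088	SYN0089	SYN0092	SYN0093	SYN0094	SYN0095	SYN0096	SYN0097	SYN0098	SYN0099	SYN0100
BLOCK_PROCESS_6	synthetic gene set (BLOCK_PROCESS_6)	SYN0101	SYN0102	SYN0103	SYN0104	SYN0106	SYN0107	SYN0110	SYN0111	SYN0112	SYN0113	SYN0114	SYN0115	SYN0116	SYN0117	SYN0119	SYN0120
RANDOM_SET_1	synthetic gene set (RANDOM_SET_1)	SYN0009	SYN0025	SYN0042	SYN0048	SYN0072	SYN0073	SYN0079	SYN0080	SYN0093	SYN0094	SYN0113	SYN0120
RANDOM_SET_2	synthetic gene set (RANDOM_SET_2)	SYN0006	SYN0013	SYN0022	SYN0035	SYN0046	SYN0051	SYN0059	SYN0076	SYN0090	SYN0097	SYN0100	SYN0115
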