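SYN0001	SYN0004
SYN0001	SYN0006
SYN0001	SYN0007
SYN0001	SYN0008
SYN0001	SYN0015
SYN0001	SYN0019
SYN0001	SYN0031
SYN0002	SYN0003
SYN0002	SYN0004
SYN0002	SYN0006
SYN0002	SYN0011
SYN0002	SYN0012
SYN0002	SYN0019
SYN0002	SYN0036
SYN0002	SYN0065
SYN0002	SYN0096
SYN0003	SYN0005
SYN0003	SYN0007
SYN0003	SYN0012
SYN0003	SYN0015
SYN0003	SYN0016
SYN0003	SYN0093
SYN0003	SYN0100
SYN0004	SYN0006
SYN0004	SYN0009
SYN0004	SYN0017
SYN0004	SYN0047
SYN0005	SYN0008
SYN0005	SYN0009
SYN0005	SYN0012
SYN0005	SYN0013
SYN0005	SYN0014
SYN0005	SYN0016
SYN0005	SYN0050
SYN0005	SYN0098
SYN0005	SYN0103
SYN0005	SYN0108
SYN0006	SYN0009
SYN0006	SYN0012
SYN0006	SYN0020
SYN0006	SYN0089
SYN0006	SYN0107
SYN0007	SYN0018
SYN0007	SYN0033
SYN0007	SYN0093
SYN0007	SYN0110
SYN0007	SYN0120
SYN0008	SYN0014
SYN0008	SYN0016
SYN0008	SYN0017
SYN0008	SYN0079
SYN0009	SYN0013
SYN0009	SYN0014
SYN0009	SYN0015
SYN0009	SYN0018
SYN0010	SYN0017
SYN0010	SYN0045
SYN0011	SYN0018
SYN0011	SYN0020
SYN0011	SYN0060
SYN0012	SYN0020
SYN0012	SYN0075
SYN0012	SYN0115
SYN0013	SYN0018
SYN0013	SYN0061
SYN0014	SYN0016
SYN0014	SYN0054
SYN0015	SYN0018
SYN0015	SYN0080
SYN0015	SYN0084
SYN0015	SYN0110
SYN0016	SYN0019
SYN0016	SYN0027
SYN0016	SYN0064
SYN0017	SYN0018
SYN0017	SYN0020
SYN0017	SYN0092
SYN0017	SYN0099
SYN0018	SYN0047
SYN0018	SYN0070
SYN0018	SYN0096
SYN0019	SYN0020
SYN0019	SYN0097
SYN0020	SYN0039
SYN0021	SYN0023
SYN0021	SYN0028
SYN0021	SYN0030
SYN0021	SYN0032
SYN0021	SYN0037
SYN0021	SYN0038
SYN0021	SYN0039
SYN0022	SYN0025
SYN0022	SYN0027
SYN0022	SYN0033
SYN0022	SYN0036
SYN0023	SYN0025
SYN0023	SYN0028
SYN0023	SYN0030
SYN0023	SYN0031
SYN0023	SYN0038
SYN0023	SYN0040
SYN0024	SYN0026
SYN0024	SYN0031
SYN0024	SYN0035
SYN0024	SYN0111
SYN0025	SYN0033
SYN0025	SYN0036
SYN0025	SYN0037
SYN0025	SYN0096
SYN0026	SYN0028
SYN0026	SYN0030
SYN0026	SYN0066
SYN0026	SYN0088
SYN0027	SYN0028
SYN0027	SYN0032
SYN0027	SYN0033
SYN0027	SYN0037
SYN0027	SYN0040
SYN0027	SYN0059
SYN0028	SYN0029
SYN0028	SYN0032
SYN0028	SYN0033
SYN0028	SYN0034
SYN0028	SYN0035
SYN0028	SYN0037
SYN0028	SYN0038
SYN0028	SYN0039
SYN0029	SYN0032
SYN0029	SYN0037
SYN0029	SYN0039
SYN0029	SYN0085
SYN0030	SYN0034
SYN0030	SYN0037
SYN0030	SYN0038
SYN0031	SYN0032
SYN0031	SYN0036
SYN0032	SYN0034
SYN0032	SYN0036
SYN0032	SYN0038
SYN0032	SYN0040
SYN0032	SYN0094
SYN0033	SYN0036
SYN0033	SYN0083
SYN0034	SYN0035
SYN0034	SYN0038
SYN0034	SYN0060
SYN0034	SYN0085
SYN0034	SYN0109
SYN0035	SYN0036
SYN0035	SYN0064
SYN0036	SYN0038
SYN0036	SYN0040
SYN0036	SYN0074
SYN0036	SYN0078
SYN0036	SYN0120
SYN0037	SYN0039
SYN0037	SYN0040
SYN0037	SYN0082
SYN0038	SYN0039
SYN0038	SYN0049
SYN0038	SYN0073
SYN0038	SYN0074
SYN0038	SYN0120
SYN0039	SYN0040
SYN0039	SYN0059
SYN0039	SYN0084
SYN0041	SYN0046
SYN0041	SYN0047
SYN0041	SYN0052
SYN0041	SYN0054
SYN0041	SYN0056
SYN0041	SYN0059
SYN0041	SYN0108
SYN0042	SYN0046
SYN0042	SYN0047
SYN0042	SYN0050
SYN0042	SYN0058
SYN0042	SYN0059
SYN0042	SYN0077
SYN0043	SYN0047
SYN0043	SYN0053
SYN0043	SYN0056
SYN0043	SYN0059
SYN0043	SYN0060
SYN0043	SYN0071
SYN0044	SYN0045
SYN0044	SYN0046
SYN0044	SYN0053
SYN0044	SYN0058
SYN0044	SYN0060
SYN0044	SYN0107
SYN0045	SYN0051
SYN0045	SYN0055
SYN0045	SYN0059
SYN0046	SYN0048
SYN0046	SYN0054
SYN0046	SYN0056
SYN0046	SYN0061
SYN0047	SYN0052
SYN0047	SYN0057
SYN0047	SYN0058
SYN0048	SYN0050
SYN0048	SYN0051
SYN0048	SYN0054
SYN0048	SYN0065
SYN0048	SYN0081
SYN0049	SYN0053
SYN0049	SYN0054
SYN0049	SYN0056
SYN0050	SYN0051
SYN0050	SYN0054
SYN0050	SYN0060
SYN0052	SYN0054
SYN0052	SYN0058
SYN0052	SYN0059
SYN0052	SYN0074
SYN0052	SYN0085
SYN0052	SYN0111
SYN0053	SYN0054
SYN0053	SYN0058
SYN0053	SYN0060
SYN0053	SYN0109
SYN0054	SYN0056
SYN0054	SYN0096
SYN0054	SYN0105
SYN0055	SYN0059
SYN0055	SYN0060
SYN0056	SYN0059
SYN0056	SYN0060
SYN0056	SYN0066
SYN0056	SYN0072
SYN0057	SYN0058
SYN0059	SYN0060
SYN0061	SYN0063
SYN0061	SYN0064
SYN0061	SYN0065
SYN0061	SYN0068
SYN0061	SYN0071
SYN0061	SYN0076
SYN0062	SYN0064
SYN0062	SYN0069
SYN0062	SYN0074
SYN0062	SYN0075
SYN0062	SYN0076
SYN0062	SYN0078
SYN0062	SYN0083
SYN0062	SYN0109
SYN0063	SYN0064
SYN0063	SYN0066
SYN0063	SYN0074
SYN0063	SYN0079
SYN0063	SYN0080
SYN0064	SYN0065
SYN0064	SYN0066
SYN0064	SYN0071
SYN0064	SYN0072
SYN0064	SYN0073
SYN0064	SYN0074
SYN0064	SYN0076
SYN0064	SYN0080
SYN0065	SYN0066
SYN0065	SYN0071
SYN0065	SYN0072
SYN0065	SYN0073
SYN0065	SYN0074
SYN0066	SYN0067
SYN0066	SYN0069
SYN0066	SYN0077
SYN0066	SYN0080
SYN0066	SYN0099
SYN0066	SYN0105
SYN0067	SYN0069
SYN0067	SYN0070
SYN0067	SYN0075
SYN0067	SYN0078
SYN0067	SYN0080
SYN0068	SYN0073
SYN0068	SYN0079
SYN0068	SYN0080
SYN0068	SYN0108
SYN0068	SYN0113
SYN0069	SYN0072
SYN0069	SYN0074
SYN0069	SYN0080
SYN0070	SYN0075
SYN0070	SYN0077
SYN0070	SYN0080
SYN0070	SYN0086
SYN0071	SYN0072
SYN0071	SYN0073
SYN0071	SYN0074
SYN0071	SYN0076
SYN0072	SYN0076
SYN0072	SYN0080
SYN0073	SYN0077
SYN0073	SYN0079
SYN0073	SYN0093
SYN0073	SYN0106
SYN0073	SYN0111
SYN0074	SYN0077
SYN0074	SYN0080
SYN0075	SYN0076
SYN0075	SYN0077
SYN0075	SYN0078
SYN0075	SYN0096
SYN0075	SYN0119
SYN0077	SYN0102
SYN0080	SYN0106
SYN0081	SYN0082
SYN0081	SYN0095
SYN0082	SYN0084
SYN0082	SYN0090
SYN0082	SYN0097
SYN0082	SYN0099
SYN0083	SYN0086
SYN0083	SYN0090
SYN0083	SYN0094
SYN0083	SYN0096
SYN0083	SYN0097
SYN0083	SYN0098
SYN0083	SYN0099
SYN0083	SYN0100
SYN0084	SYN0092
SYN0084	SYN0093
SYN0084	SYN0094
SYN0084	SYN0095
SYN0084	SYN0096
SYN0084	SYN0099
SYN0084	SYN0100
SYN0085	SYN0086
SYN0085	SYN0088
SYN0085	SYN0092
SYN0085	SYN0093
SYN0085	SYN0097
SYN0085	SYN0099
SYN0086	SYN0087
SYN0086	SYN0095
SYN0087	SYN0090
SYN0087	SYN0092
SYN0087	SYN0098
SYN0087	SYN0119
SYN0088	SYN0103
SYN0088	SYN0117
SYN0089	SYN0090
SYN0089	SYN0091
SYN0090	SYN0092
SYN0090	SYN0094
SYN0090	SYN0097
SYN0090	SYN0100
SYN0091	SYN0095
SYN0091	SYN0097
SYN0092	SYN0093
SYN0092	SYN0095
SYN0092	SYN0098
SYN0092	SYN0115
SYN0093	SYN0099
SYN0093	SYN0111
SYN0094	SYN0095
SYN0094	SYN0098
SYN0094	SYN0099
SYN0094	SYN0100
SYN0095	SYN0097
SYN0096	SYN0098
SYN0096	SYN0100
SYN0096	SYN0102
SYN0097	SYN0100
SYN0099	SYN0100
SYN0100	SYN0117
SYN0101	SYN0109
SYN0101	SYN0111
SYN0101	SYN0114
SYN0101	SYN0118
SYN0101	SYN0120
SYN0102	SYN0106
SYN0102	SYN0107
SYN0102	SYN0110
SYN0102	SYN0115
SYN0102	SYN0116
SYN0102	SYN0117
SYN0102	SYN0118
SYN0103	SYN0104
SYN0103	SYN0108
SYN0103	SYN0115
SYN0103	SYN0116
SYN0104	SYN0107
SYN0105	SYN0114
SYN0105	SYN0115
SYN0105	SYN0117
SYN0105	SYN0119
SYN0106	SYN0111
SYN0106	SYN0116
SYN0106	SYN0119
SYN0107	SYN0108
SYN0107	SYN0109
SYN0107	SYN0114
SYN0107	SYN0119
SYN0107	SYN0120
SYN0108	SYN0110
SYN0108	SYN0117
SYN0108	SYN0119
SYN0108	SYN0120
SYN0109	SYN0114
SYN0109	SYN0117
SYN0110	SYN0115
SYN0110	SYN0116
SYN0110	SYN0119
SYN0111	SYN0114
SYN0111	SYN0118
SYN0111	SYN0120
SYN0112	SYN0113
SYN0112	SYN0115
SYN0113	SYN0114
SYN0113	SYN0116
SYN0113	SYN0119
SYN0114	SYN0115
SYN0114	SYN0116
SYN0114	SYN0117
SYN0114	SYN0119
SYN0116	SYN0120
SYN0117	SYN0118
SYN0117	SYN0120
SYN0118	SYN0119
SYN0118	SYN0120
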