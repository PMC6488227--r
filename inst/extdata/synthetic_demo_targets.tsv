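family_id	gene_symbol
miR-001	SYN0005
miR-001	SYN0008
miR-001	SYN0009
miR-001	SYN0015
miR-001	SYN0024
miR-001	SYN0026
miR-001	SYN0028
miR-001	SYN0030
miR-001	SYN0047
miR-001	SYN0056
miR-001	SYN0057
miR-001	SYN0058
miR-001	SYN0063
miR-001	SYN0064
miR-001	SYN0069
miR-001	SYN0080
miR-001	SYN0087
miR-001	SYN0088
miR-001	SYN0094
miR-001	SYN0096
miR-001	SYN0105
miR-001	SYN0106
miR-001	SYN0107
miR-001	SYN0117
miR-002	SYN0001
miR-002	SYN0003
miR-002	SYN0004
miR-002	SYN0005
miR-002	SYN0006
miR-002	SYN0007
miR-002	SYN0008
miR-002	SYN0009
miR-002	SYN0013
miR-002	SYN0015
miR-002	SYN0018
miR-002	SYN0020
miR-002	SYN0062
miR-002	SYN0063
miR-002	SYN0064
miR-002	SYN0066
miR-002	SYN0067
miR-002	SYN0068
miR-002	SYN0069
miR-002	SYN0070
miR-002	SYN0071
miR-002	SYN0072
miR-002	SYN0074
miR-002	SYN0080
miR-003	SYN0006
miR-003	SYN0025
miR-003	SYN0026
miR-003	SYN0031
miR-003	SYN0033
miR-003	SYN0036
miR-003	SYN0044
miR-003	SYN0052
miR-003	SYN0053
miR-003	SYN0057
miR-003	SYN0069
miR-003	SYN0078
miR-003	SYN0080
miR-003	SYN0085
miR-003	SYN0092
miR-003	SYN0098
miR-003	SYN0102
miR-003	SYN0105
miR-003	SYN0108
miR-003	SYN0109
miR-003	SYN0111
miR-003	SYN0112
miR-003	SYN0117
miR-003	SYN0119
miR-004	SYN0003
miR-004	SYN0013
miR-004	SYN0016
miR-004	SYN0021
miR-004	SYN0022
miR-004	SYN0023
miR-004	SYN0026
miR-004	SYN0027
miR-004	SYN0038
miR-004	SYN0040
miR-004	SYN0045
miR-004	SYN0051
miR-004	SYN0052
miR-004	SYN0053
miR-004	SYN0059
miR-004	SYN0060
miR-004	SYN0063
miR-004	SYN0073
miR-004	SYN0076
miR-004	SYN0083
miR-004	SYN0097
miR-004	SYN0108
miR-004	SYN0111
miR-004	SYN0113
miR-005	SYN0005
miR-005	SYN0011
miR-005	SYN0013
miR-005	SYN0014
miR-005	SYN0022
miR-005	SYN0023
miR-005	SYN0026
miR-005	SYN0029
miR-005	SYN0032
miR-005	SYN0045
miR-005	SYN0048
miR-005	SYN0052
miR-005	SYN0058
miR-005	SYN0062
miR-005	SYN0063
miR-005	SYN0067
miR-005	SYN0068
miR-005	SYN0071
miR-005	SYN0076
miR-005	SYN0082
miR-005	SYN0094
miR-005	SYN0101
miR-005	SYN0112
miR-005	SYN0120
miR-006	SYN0005
miR-006	SYN0013
miR-006	SYN0018
miR-006	SYN0020
miR-006	SYN0026
miR-006	SYN0034
miR-006	SYN0037
miR-006	SYN0047
miR-006	SYN0048
miR-006	SYN0049
miR-006	SYN0054
miR-006	SYN0060
miR-006	SYN0062
miR-006	SYN0072
miR-006	SYN0078
miR-006	SYN0085
miR-006	SYN0088
miR-006	SYN0094
miR-006	SYN0095
miR-006	SYN0097
miR-006	SYN0104
miR-006	SYN0114
miR-006	SYN0117
miR-006	SYN0120
miR-007	SYN0018
miR-007	SYN0019
miR-007	SYN0025
miR-007	SYN0030
miR-007	SYN0039
miR-007	SYN0043
miR-007	SYN0044
miR-007	SYN0045
miR-007	SYN0052
miR-007	SYN0053
miR-007	SYN0056
miR-007	SYN0057
miR-007	SYN0060
miR-007	SYN0062
miR-007	SYN0069
miR-007	SYN0083
miR-007	SYN0091
miR-007	SYN0099
miR-007	SYN0103
miR-007	SYN0107
miR-007	SYN0111
miR-007	SYN0117
miR-007	SYN0118
miR-007	SYN0120
miR-008	SYN0002
miR-008	SYN0011
miR-008	SYN0012
miR-008	SYN0020
miR-008	SYN0022
miR-008	SYN0023
miR-008	SYN0033
miR-008	SYN0036
miR-008	SYN0038
miR-008	SYN0043
miR-008	SYN0062
miR-008	SYN0065
miR-008	SYN0076
miR-008	SYN0079
miR-008	SYN0081
miR-008	SYN0091
miR-008	SYN0096
miR-008	SYN0099
miR-008	SYN0102
miR-008	SYN0103
miR-008	SYN0106
miR-008	SYN0108
miR-008	SYN0118
miR-008	SYN0119
miR-009	SYN0009
miR-009	SYN0012
miR-009	SYN0018
miR-009	SYN0021
miR-009	SYN0022
miR-009	SYN0024
miR-009	SYN0030
miR-009	SYN0041
miR-009	SYN0050
miR-009	SYN0051
miR-009	SYN0052
miR-009	SYN0056
miR-009	SYN0067
miR-009	SYN0069
miR-009	SYN0073
miR-009	SYN0074
miR-009	SYN0077
miR-009	SYN0092
miR-009	SYN0096
miR-009	SYN0098
miR-009	SYN0100
miR-009	SYN0106
miR-009	SYN0114
miR-009	SYN0120
miR-010	SYN0003
miR-010	SYN0010
miR-010	SYN0015
miR-010	SYN0016
miR-010	SYN0022
miR-010	SYN0027
miR-010	SYN0034
miR-010	SYN0035
miR-010	SYN0040
miR-010	SYN0047
miR-010	SYN0049
miR-010	SYN0056
miR-010	SYN0060
miR-010	SYN0061
miR-010	SYN0065
miR-010	SYN0070
miR-010	SYN0072
miR-010	SYN0091
miR-010	SYN0097
miR-010	SYN0098
miR-010	SYN0105
miR-010	SYN0107
miR-010	SYN0113
miR-010	SYN0116
miR-011	SYN0002
miR-011	SYN0010
miR-011	SYN0034
miR-011	SYN0037
miR-011	SYN0038
miR-011	SYN0039
miR-011	SYN0044
miR-011	SYN0049
miR-011	SYN0053
miR-011	SYN0066
miR-011	SYN0068
miR-011	SYN0076
miR-011	SYN0078
miR-011	SYN0079
miR-011	SYN0080
miR-011	SYN0082
miR-011	SYN0096
miR-011	SYN0097
miR-011	SYN0098
miR-011	SYN0101
miR-011	SYN0102
miR-011	SYN0104
miR-011	SYN0108
miR-011	SYN0117
miR-012	SYN0004
miR-012	SYN0005
miR-012	SYN0008
miR-012	SYN0013
miR-012	SYN0024
miR-012	SYN0031
miR-012	SYN0033
miR-012	SYN0044
miR-012	SYN0052
miR-012	SYN0053
miR-012	SYN0057
miR-012	SYN0068
miR-012	SYN0071
miR-012	SYN0075
miR-012	SYN0076
miR-012	SYN0078
miR-012	SYN0081
miR-012	SYN0082
miR-012	SYN0090
miR-012	SYN0091
miR-012	SYN0105
miR-012	SYN0107
miR-012	SYN0118
miR-012	SYN0119
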