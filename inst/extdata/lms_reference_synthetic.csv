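sex,age_years,L,M,S
F,2,-1.2,15.75,0.08
F,3,-1.249,15.966,0.0839
F,4,-1.296,16.098,0.0876
F,5,-1.341,16.177,0.0911
F,6,-1.384,16.522,0.0944
F,7,-1.425,16.839,0.0975
F,8,-1.464,17.137,0.1004
F,9,-1.501,17.419,0.1031
F,10,-1.536,17.69,0.1056
F,11,-1.569,17.95,0.1079
F,12,-1.6,18.2,0.11
F,13,-1.629,18.442,0.1119
F,14,-1.656,18.675,0.1136
F,15,-1.681,18.899,0.1151
F,16,-1.704,19.115,0.1164
F,17,-1.725,19.324,0.1175
F,18,-1.744,19.524,0.1184
M,2,-1.1,15.9,0.078
M,3,-1.149,16.116,0.0819
M,4,-1.196,16.248,0.0856
M,5,-1.241,16.327,0.0891
M,6,-1.284,16.672,0.0924
M,7,-1.325,16.989,0.0955
M,8,-1.364,17.287,0.0984
M,9,-1.401,17.569,0.1011
M,10,-1.436,17.84,0.1036
M,11,-1.469,18.1,0.1059
M,12,-1.5,18.35,0.108
M,13,-1.529,18.592,0.1099
M,14,-1.556,18.825,0.1116
M,15,-1.581,19.049,0.1131
M,16,-1.604,19.265,0.1144
M,17,-1.625,19.474,0.1155
M,18,-1.644,19.674,0.1164
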