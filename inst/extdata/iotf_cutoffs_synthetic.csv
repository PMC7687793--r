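sex,age_years,bmi_underweight,bmi_overweight,bmi_obesity
F,2,13.886,17.285,18.812
F,3,14.002,17.611,19.274
F,4,14.049,17.843,19.637
F,5,14.054,18.015,19.936
F,6,14.293,18.482,20.564
F,7,14.511,18.917,21.161
F,8,14.715,19.331,21.737
F,9,14.909,19.725,22.294
F,10,15.096,20.105,22.835
F,11,15.278,20.469,23.361
F,12,15.453,20.82,23.869
F,13,15.626,21.158,24.361
F,14,15.794,21.481,24.834
F,15,15.958,21.79,25.285
F,16,16.118,22.085,25.714
F,17,16.276,22.367,26.12
F,18,16.43,22.632,26.499
M,2,14.049,17.4,18.868
M,3,14.163,17.724,19.323
M,4,14.208,17.955,19.679
M,5,14.211,18.126,19.97
M,6,14.449,18.59,20.588
M,7,14.666,19.024,21.174
M,8,14.869,19.435,21.739
M,9,15.061,19.827,22.284
M,10,15.248,20.204,22.814
M,11,15.428,20.567,23.327
M,12,15.603,20.915,23.823
M,13,15.774,21.251,24.303
M,14,15.942,21.572,24.764
M,15,16.105,21.879,25.203
M,16,16.265,22.172,25.62
M,17,16.423,22.452,26.015
M,18,16.576,22.716,26.384
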