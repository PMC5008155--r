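individual_id,age_days,body_mass_g,survived_to_1yr
M00037,,,FALSE
M00038,,,FALSE
M00039,,,FALSE
M00040,,,FALSE
M00041,,,FALSE
M00042,,,FALSE
M00043,,,FALSE
M00044,,,FALSE
M00045,,,FALSE
M00046,350,1163.9,TRUE
M00046,350,1240.8,TRUE
M00046,359,1214.2,TRUE
M00046,365,1261.9,TRUE
M00046,365,1358.8,TRUE
M00046,370,1270.5,TRUE
M00047,,,FALSE
M00048,352,1278.7,TRUE
M00048,354,1038.5,TRUE
M00048,357,1078.8,TRUE
M00048,359,1217.4,TRUE
M00048,359,1134.3,TRUE
M00048,364,1197.2,TRUE
M00048,367,1085.1,TRUE
M00048,370,1229.6,TRUE
M00049,,,FALSE
M00050,,,FALSE
M00051,352,1129.1,TRUE
M00051,354,1255.4,TRUE
M00051,360,1159.6,TRUE
M00052,357,1057.8,TRUE
M00052,367,1279.9,TRUE
M00053,,,FALSE
M00054,364,1068.8,TRUE
M00054,365,1053.6,TRUE
M00054,370,1175.1,TRUE
M00055,,,FALSE
M00056,,,FALSE
M00057,,,FALSE
M00058,,,FALSE
M00059,,,FALSE
M00060,366,1080.8,TRUE
M00061,,,FALSE
M00062,,,FALSE
M00063,350,917,TRUE
M00063,350,1023.9,TRUE
M00063,351,863.3,TRUE
M00063,360,933.3,TRUE
M00063,364,988.5,TRUE
M00063,365,787.7,TRUE
M00063,366,980.5,TRUE
M00063,370,966.2,TRUE
M00064,,,FALSE
M00065,,,FALSE
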