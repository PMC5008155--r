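offspring_id,attempt_id,dam_id,sire_id,dam_confidence,sire_confidence
M00013,,M00002,M00004,1,1
M00014,,M00002,M00004,1,1
M00015,,M00002,M00004,1,1
M00016,,M00002,M00004,1,1
M00017,,M00007,M00012,1,1
M00018,,M00007,M00012,1,1
M00019,,M00007,M00012,1,1
M00020,,M00007,M00012,1,1
M00021,,M00007,M00012,1,1
M00022,,M00009,M00006,1,1
M00023,,M00001,M00006,1,1
M00024,,M00001,M00006,1,1
M00025,,M00001,M00006,1,1
M00026,,M00001,M00006,1,1
M00027,,M00008,M00010,1,1
M00028,,M00008,M00010,1,1
M00029,,M00008,M00010,1,1
M00030,,M00008,M00010,1,1
M00031,,M00008,M00012,1,1
M00032,,M00002,M00004,1,1
M00033,,M00002,M00004,1,1
M00034,,M00002,M00004,1,1
M00035,,M00008,M00012,1,1
M00036,,M00008,M00012,1,1
M00037,AT0001,M00001,M00006,1,1
M00038,AT0001,M00001,M00006,1,1
M00039,AT0001,M00001,M00006,1,1
M00040,AT0001,M00002,M00006,1,1
M00041,AT0001,M00002,M00006,1,1
M00042,AT0001,M00002,M00006,1,1
M00043,AT0002,M00009,M00010,1,1
M00044,AT0003,M00002,M00005,1,1
M00045,AT0003,M00002,M00005,1,1
M00046,AT0003,M00002,M00005,1,1
M00047,AT0004,M00009,M00010,1,1
M00048,AT0004,M00009,M00010,1,1
M00049,AT0004,M00009,M00010,1,1
M00050,AT0004,M00009,M00010,1,1
M00051,AT0005,M00001,M00005,1,1
M00052,AT0005,M00001,M00005,1,1
M00053,AT0005,M00001,M00005,1,1
M00054,AT0005,M00001,M00005,1,1
M00055,AT0005,M00001,M00005,1,1
M00056,AT0006,M00019,M00012,1,1
M00057,AT0006,M00019,M00012,1,1
M00058,AT0007,M00016,M00005,1,1
M00059,AT0007,M00016,M00005,1,1
M00060,AT0007,M00016,M00005,1,1
M00061,AT0007,M00016,M00005,1,1
M00062,AT0008,M00019,M00012,1,1
M00063,AT0008,M00019,M00012,1,1
M00064,AT0008,M00019,M00012,1,1
M00065,AT0008,M00019,M00012,1,1
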