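id,dam,sire,sex,birth_date,natal_group
M00001,,,F,2001-02-14,
M00002,,,F,2000-12-13,
M00003,,,F,1997-08-02,
M00004,,,M,1998-12-17,
M00005,,,M,1998-01-26,
M00006,,,M,1999-05-31,
M00007,,,F,1998-03-14,
M00008,,,F,1997-06-17,
M00009,,,F,1999-10-01,
M00010,,,M,2001-01-07,
M00011,,,M,1997-08-14,
M00012,,,M,1999-08-19,
M00013,M00002,M00004,F,2002-06-02,G1
M00014,M00002,M00004,F,2002-06-02,G1
M00015,M00002,M00004,F,2002-06-02,G1
M00016,M00002,M00004,F,2002-06-02,G1
M00032,M00002,M00004,F,2002-12-01,G1
M00033,M00002,M00004,F,2002-12-01,G1
M00034,M00002,M00004,F,2002-12-01,G1
M00044,M00002,M00005,F,2003-06-01,G1
M00045,M00002,M00005,M,2003-06-01,G1
M00046,M00002,M00005,M,2003-06-01,G1
M00051,M00001,M00005,F,2003-08-31,G1
M00052,M00001,M00005,M,2003-08-31,G1
M00053,M00001,M00005,F,2003-08-31,G1
M00054,M00001,M00005,M,2003-08-31,G1
M00055,M00001,M00005,F,2003-08-31,G1
M00023,M00001,M00006,M,2002-09-01,G1
M00024,M00001,M00006,M,2002-09-01,G1
M00025,M00001,M00006,M,2002-09-01,G1
M00026,M00001,M00006,M,2002-09-01,G1
M00037,M00001,M00006,F,2003-03-02,G1
M00038,M00001,M00006,M,2003-03-02,G1
M00039,M00001,M00006,F,2003-03-02,G1
M00040,M00002,M00006,M,2003-03-02,G1
M00041,M00002,M00006,F,2003-03-02,G1
M00042,M00002,M00006,F,2003-03-02,G1
M00022,M00009,M00006,M,2002-06-12,G2
M00027,M00008,M00010,F,2002-09-11,G2
M00028,M00008,M00010,F,2002-09-11,G2
M00029,M00008,M00010,M,2002-09-11,G2
M00030,M00008,M00010,F,2002-09-11,G2
M00043,M00009,M00010,M,2003-03-12,G2
M00047,M00009,M00010,F,2003-06-11,G2
M00048,M00009,M00010,M,2003-06-11,G2
M00049,M00009,M00010,M,2003-06-11,G2
M00050,M00009,M00010,F,2003-06-11,G2
M00017,M00007,M00012,M,2002-06-12,G2
M00018,M00007,M00012,F,2002-06-12,G2
M00019,M00007,M00012,F,2002-06-12,G2
M00020,M00007,M00012,M,2002-06-12,G2
M00021,M00007,M00012,F,2002-06-12,G2
M00031,M00008,M00012,M,2002-09-11,G2
M00035,M00008,M00012,F,2002-12-11,G2
M00036,M00008,M00012,M,2002-12-11,G2
M00058,M00016,M00005,F,2003-11-30,G1
M00059,M00016,M00005,F,2003-11-30,G1
M00060,M00016,M00005,F,2003-11-30,G1
M00061,M00016,M00005,M,2003-11-30,G1
M00056,M00019,M00012,F,2003-09-10,G2
M00057,M00019,M00012,M,2003-09-10,G2
M00062,M00019,M00012,F,2003-12-10,G2
M00063,M00019,M00012,M,2003-12-10,G2
M00064,M00019,M00012,M,2003-12-10,G2
M00065,M00019,M00012,M,2003-12-10,G2
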