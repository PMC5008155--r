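group_id,attempt_id,individual_id,sex,is_natal
G1,AT0001,M00001,F,FALSE
G1,AT0001,M00002,F,FALSE
G1,AT0001,M00005,M,FALSE
G1,AT0001,M00006,M,FALSE
G2,AT0002,M00009,F,FALSE
G2,AT0002,M00010,M,FALSE
G2,AT0002,M00012,M,FALSE
G1,AT0003,M00001,F,FALSE
G1,AT0003,M00002,F,FALSE
G1,AT0003,M00005,M,FALSE
G1,AT0003,M00006,M,FALSE
G2,AT0004,M00009,F,FALSE
G2,AT0004,M00010,M,FALSE
G2,AT0004,M00012,M,FALSE
G1,AT0005,M00001,F,FALSE
G1,AT0005,M00002,F,FALSE
G1,AT0005,M00005,M,FALSE
G1,AT0005,M00016,F,TRUE
G2,AT0006,M00009,F,FALSE
G2,AT0006,M00010,M,FALSE
G2,AT0006,M00012,M,FALSE
G2,AT0006,M00019,F,TRUE
G2,AT0006,M00020,M,TRUE
G1,AT0007,M00001,F,FALSE
G1,AT0007,M00002,F,FALSE
G1,AT0007,M00005,M,FALSE
G1,AT0007,M00016,F,TRUE
G2,AT0008,M00009,F,FALSE
G2,AT0008,M00010,M,FALSE
G2,AT0008,M00012,M,FALSE
G2,AT0008,M00019,F,TRUE
G2,AT0008,M00027,F,TRUE
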