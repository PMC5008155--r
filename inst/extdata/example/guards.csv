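attempt_id,guard_id,female_id,n_days_guarding
AT0001,M00005,M00001,1
AT0001,M00006,M00001,4
AT0001,M00006,M00002,3
AT0002,M00012,M00009,2
AT0003,M00006,M00001,1
AT0003,M00005,M00002,1
AT0003,M00006,M00002,3
AT0004,M00012,M00009,4
AT0005,M00005,M00001,1
AT0006,M00020,M00019,3
AT0006,M00012,M00019,1
AT0006,M00010,M00019,3
AT0007,M00005,M00016,3
AT0008,M00010,M00019,2
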