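attempt_id,group_id,oestrus_start_date,birth_date,rainfall_30d,group_size_adults,n_pups_born
AT0001,G1,2003-01-01,2003-03-02,1.981,4,6
AT0002,G2,2003-01-11,2003-03-12,2.844,3,1
AT0003,G1,2003-04-02,2003-06-01,2.956,4,3
AT0004,G2,2003-04-12,2003-06-11,5.34,3,4
AT0005,G1,2003-07-02,2003-08-31,1.967,4,5
AT0006,G2,2003-07-12,2003-09-10,1.885,5,2
AT0007,G1,2003-10-01,2003-11-30,3.02,4,4
AT0008,G2,2003-10-11,2003-12-10,2.341,5,4
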