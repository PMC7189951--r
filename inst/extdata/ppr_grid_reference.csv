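C_years,t0_1,t1_2,t2_3,t3_4
5,0.918,0.820,0.557,0.307
6,0.925,0.832,0.568,0.315
7,0.944,0.849,0.574,0.347
8,0.967,0.851,0.580,0.351
9,0.981,0.854,0.596,0.361
10,0.983,0.861,0.592,0.354
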