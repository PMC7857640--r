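trial,k_w,c_wall
1,23.727,NA
2,48.112,2.172
3,63.173,2.237
4,23.170,NA
5,29.646,2.195
6,78.167,2.196
7,21.005,NA
8,33.066,NA
9,32.606,2.194
10,39.661,2.502
11,33.658,2.158
12,32.696,NA
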