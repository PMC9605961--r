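voice_type,structure,n,fhe_mean,fhe_sd,fhe_rr_low,fhe_rr_high,phe_mean,phe_sd,phe_rr_low,phe_rr_high,sc_mean,sc_sd,sc_rr_low,sc_rr_high
soprano,all,774,3092,284,3072,3112,35.98,12.92,35.07,36.89,3207,154,3196,3218
soprano,lyric,352,3169,307,3136,3201,39.46,13.94,38.00,40.92,3271,159,3255,3288
soprano,dramatic,422,3028,247,3004,3052,33.08,11.23,32.00,34.15,3153,128,3141,3166
tenor,all,389,2705,221,2683,2727,44.05,13.82,42.67,45.43,2740,143,2725,2754
tenor,lyric,199,2760,205,2732,2789,47.49,12.77,45.70,49.28,2789,129,2771,2807
tenor,dramatic,190,2648,224,2616,2680,40.45,13.99,38.45,42.45,2688,139,2668,2708
baritone,all,343,2454,206,2432,2476,28.34,12.86,26.98,29.71,2532,144,2516,2547
baritone,lyric,157,2576,206,2543,2608,35.94,12.86,33.91,37.97,2625,135,2604,2646
baritone,dramatic,186,2351,140,2331,2371,21.93,8.72,20.67,23.20,2453,97,2439,2467
bass,all,217,2384,164,2363,2406,24.01,10.24,22.64,25.38,2480,92,2468,2493
bass,lyric,60,2379,200,2327,2430,23.65,12.46,20.43,26.87,2491,98,2466,2516
bass,dramatic,157,2387,149,2363,2410,24.15,9.30,22.68,25.61,2476,89,2462,2490
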