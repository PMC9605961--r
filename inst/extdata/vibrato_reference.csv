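voice_type,structure,vr_mean,vr_sd,ve_mean,ve_sd,source
soprano,lyric,6.38,0.86,76.30,28.9,published_rr
soprano,dramatic,6.17,0.68,99.07,34.7,published_rr
tenor,lyric,6.26,0.61,75.30,25.9,published_rr
tenor,dramatic,6.01,0.53,83.23,21.5,published_rr
baritone,lyric,6.11,0.64,107.35,31.7,published_rr
baritone,dramatic,6.00,0.60,85.00,25.0,assumed
bass,lyric,5.90,0.60,90.00,30.0,assumed
bass,dramatic,5.90,0.60,90.00,30.0,assumed
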