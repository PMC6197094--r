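stage,K,se_K,D0,se_D0,r2,note
egg,207.2,7.2,10.91,0.34,0.99,
instar1,272.0,33.9,13.35,0.79,0.98,
instar2,332.8,37.3,12.68,0.83,0.97,
instar3,1077.6,56.2,11.57,0.45,0.99,
pupa,2007.2,81.4,10.31,0.43,0.99,
total,3418.7,137.0,11.41,0.32,0.99,printed K is mutually inconsistent with the printed D0 under a regression through the mean-duration data; refitting the published mean durations gives K near 3827 at the same slope
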