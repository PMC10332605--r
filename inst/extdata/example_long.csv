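site,location,sample,replicate,detection,ct
SpringA,outlet,S1,1,1,28.4
SpringA,outlet,S1,2,1,30.1
SpringA,outlet,S1,3,0,36.2
SpringA,downstream,S2,1,0,
SpringA,downstream,S2,2,0,
SpringA,downstream,S2,3,0,
SpringB,outlet,S1,1,1,31.7
SpringB,outlet,S1,2,0,35.0
SpringB,outlet,S1,3,1,33.9
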