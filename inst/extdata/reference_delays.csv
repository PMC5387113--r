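T1,T2,T3,T4,T5,DAI,NSI,NP
2016-11-04-173424,2016-11-04-173427,2016-11-04-173427,2016-11-04-173428,2016-11-04-1734,3,0,1
2016-11-04-173430,2016-11-04-173434,2016-11-04-173434,2016-11-04-173436,2016-11-04-1735,4,0,2
2016-11-04-173442,2016-11-04-173445,2016-11-04-173445,2016-11-04-173448,2016-11-04-1735,3,0,3
2016-11-04-173450,2016-11-04-173454,2016-11-04-173454,2016-11-04-173455,2016-11-04-1735,4,0,1
2016-11-04-173458,2016-11-04-173501,2016-11-04-173501,2016-11-04-173502,2016-11-04-1735,3,0,1
2016-11-04-173504,2016-11-04-173507,2016-11-04-173507,2016-11-04-173509,2016-11-04-1735,3,0,2
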