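time,pose,status
0:00:1,1,Wander
0:00:2,2,Wander
0:00:3,3,Nervous
0:00:4,1,Depressed
0:00:5,1,Depressed
0:00:55,2,Depressed
0:00:56,2,Depressed
0:00:57,2,Nervous
0:00:58,1,Nervous
0:00:59,1,Depressed
0:00:60,1,Depressed
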