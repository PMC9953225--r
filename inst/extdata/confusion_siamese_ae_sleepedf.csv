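W,N1,N2,N3,REM
7245,370,166,39,107
534,929,884,20,437
435,257,15778,718,611
32,1,635,5021,14
200,113,642,10,6752
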