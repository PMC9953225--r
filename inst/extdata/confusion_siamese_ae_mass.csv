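W,N1,N2,N3,REM
5501,328,92,11,124
563,2344,808,8,875
163,650,25906,786,806
6,3,1326,6062,1
85,311,308,3,9498
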