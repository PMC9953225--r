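W,N1,N2,N3,REM
7103,394,225,49,156
488,928,889,14,487
330,234,15751,722,762
26,2,706,4952,17
170,120,536,35,6856
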