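ion_id,role,L1i,L1m
SCN,anion,1.38,
NTf2,anion,5.67,
Br,anion,0.00,
C4mpy,cation,,6.78
C8mim,cation,,18.4
C4mpyrr,cation,,4.48
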