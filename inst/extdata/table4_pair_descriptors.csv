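il_id,L/Bw,RTv,L3u
[C4mim][NTf2],1.98,6.69,2.29
[C4py][NTf2],1.68,6.65,1.39
[C4mpyrr][NTf2],2.3,6.75,2.13
[C4mpip][NTf2],2.03,6.82,1.39
[C8mim][NTf2],2.85,7.20,2.13
[C8py][NTf2],2.2,7.16,1.56
[C8mpyrr][NTf2],2.05,6.93,1.28
[C8mpip][NTf2],2.23,7.34,1.90
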