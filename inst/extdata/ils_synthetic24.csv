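il_id,cation_id,anion_id,n_cation,n_anion,endpoint
[C4mim][Br],C4mim,Br,1,1,
[C4mim][SCN],C4mim,SCN,1,1,
[C4mim][NTf2],C4mim,NTf2,1,1,
[C8mim][Br],C8mim,Br,1,1,
[C8mim][SCN],C8mim,SCN,1,1,
[C8mim][NTf2],C8mim,NTf2,1,1,
[C4py][Br],C4py,Br,1,1,
[C4py][SCN],C4py,SCN,1,1,
[C4py][NTf2],C4py,NTf2,1,1,
[C8py][Br],C8py,Br,1,1,
[C8py][SCN],C8py,SCN,1,1,
[C8py][NTf2],C8py,NTf2,1,1,
[C4mpy][SCN],C4mpy,SCN,1,1,
[C4mpyrr][Br],C4mpyrr,Br,1,1,
[C4mpyrr][SCN],C4mpyrr,SCN,1,1,
[C4mpyrr][NTf2],C4mpyrr,NTf2,1,1,
[C8mpyrr][Br],C8mpyrr,Br,1,1,
[C8mpyrr][SCN],C8mpyrr,SCN,1,1,
[C8mpyrr][NTf2],C8mpyrr,NTf2,1,1,
[C4mpip][Br],C4mpip,Br,1,1,
[C4mpip][SCN],C4mpip,SCN,1,1,
[C4mpip][NTf2],C4mpip,NTf2,1,1,
[C8mpip][Br],C8mpip,Br,1,1,
[C8mpip][NTf2],C8mpip,NTf2,1,1,
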