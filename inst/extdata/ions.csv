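ion_id,role,smiles,name
C4mim,cation,CCCCn1cc[n+](C)c1,1-butyl-3-methylimidazolium
C8mim,cation,CCCCCCCCn1cc[n+](C)c1,1-octyl-3-methylimidazolium
C4py,cation,CCCC[n+]1ccccc1,1-butylpyridinium
C8py,cation,CCCCCCCC[n+]1ccccc1,1-octylpyridinium
C4mpy,cation,CCCC[n+]1cccc(C)c1,1-butyl-3-methylpyridinium
C4mpyrr,cation,CCCC[N+]1(C)CCCC1,1-butyl-1-methylpyrrolidinium
C8mpyrr,cation,CCCCCCCC[N+]1(C)CCCC1,1-octyl-1-methylpyrrolidinium
C4mpip,cation,CCCC[N+]1(C)CCCCC1,1-butyl-1-methylpiperidinium
C8mpip,cation,CCCCCCCC[N+]1(C)CCCCC1,1-octyl-1-methylpiperidinium
Br,anion,[Br-],bromide
SCN,anion,[S-]C#N,thiocyanate
NTf2,anion,O=S(=O)(C(F)(F)F)[N-]S(=O)(=O)C(F)(F)F,bis(trifluoromethylsulfonyl)amide
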