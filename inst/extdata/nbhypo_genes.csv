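probeset_id,gene_symbol,accession
NM_013410,AK3L1,NM_013410
NM_005165,ALDOC,NM_005165
NM_016109,ANGPTL4,NM_016109
AA886870,ANKRD37,AA886870
NM_003670,BHLHB2,NM_003670
NM_004052,BNIP3,NM_004052
AF060922,BNIP3L,AF060922
NM_001731,BTG1,NM_001731
NM_019058,DDIT4,NM_019058
NM_014367,E2IG5,NM_014367
BC005369,EGLN1,BC005369
NM_022073,EGLN3,NM_022073
BF541967,FUT11,BF541967
H05812,IGF1R,H05812
M31159,IGFBP3,M31159
AA524505,JMJD1A,AA524505
AI056359,MAPT,AI056359
AF060924,MTP18,AF060924
NM_005962,MXI1,NM_005962
NM_006096,NDRG1,NM_006096
NM_004199,P4HA2,NM_004199
NM_002610,PDK1,NM_002610
AL038787,PFKFB4,AL038787
NM_000291,PGK1,NM_000291
NM_002633,PGM1,NM_002633
NM_000302,PLOD1,NM_000302
NM_006931,SLC2A3,NM_006931
NM_006058,TNIP1,NM_006058
NM_000365,TPI1,NM_000365
AA812232,TXNIP,AA812232
AF022375,VEGF,AF022375
NM_017606,ZNF395,NM_017606
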