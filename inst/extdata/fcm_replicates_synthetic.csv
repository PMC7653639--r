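sample_id,day,c2_pg
HAN_rubinea_01,1,2.031
HAN_rubinea_01,2,2.024
HAN_rubinea_01,3,2.019
HAN_nitens_01,1,1.262
HAN_nitens_01,2,1.291
HAN_nitens_01,3,1.279
HAN_nitens_01,4,1.275
HAN_nitens_01,5,1.273
HAN_neglecta_01,1,3.571
HAN_neglecta_01,2,3.549
HAN_neglecta_01,3,3.560
HAN_corneri_01,1,1.489
HAN_corneri_01,2,1.497
HAN_anthelminthica_01,1,2.281
HAN_anthelminthica_01,2,2.367
HAN_anthelminthica_01,3,2.296
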