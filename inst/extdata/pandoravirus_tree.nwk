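(((p_salinus:0.25,p_dulcis:0.25)4:0.10,(p_braziliensis:0.30,(p_inopinatum:0.20,(p_quercus:0.02,p_celtis:0.02)9:0.15)8:0.08)5:0.06)2:0.35,((p_neocaledonia:0.20,p_macleodensis:0.20)6:0.15,(p_pampulha:0.25,p_massiliensis:0.25)7:0.10)3:0.35)1;
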