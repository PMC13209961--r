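drug_id,target_id
Imatinib,BCR-Abl
Imatinib,PDGFRa
Imatinib,c-Kit
Sorafenib,VEGFR-2
Sorafenib,RET
Gefitinib,EGFR
Erlotinib,EGFR
Sunitinib,VEGFR-2
Sunitinib,PDGFRa
Sunitinib,c-Kit
Lapatinib,EGFR
Lapatinib,HER2
Dasatinib,BCR-Abl
Dasatinib,Src
Nilotinib,BCR-Abl
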