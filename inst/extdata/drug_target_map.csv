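drug_id,target_id
Abrocitinib,JAK1
Acalabrutinib,BTK
Afatinib,EGFR
Afatinib,HER2
Asciminib,BCR-Abl
Avapritinib,PDGFRa
Axitinib,VEGFR-2
Baricitinib,JAK2
Bosutinib,BCR-Abl
Cabozatinib,RET
Cabozatinib,VEGFR-2
Capivasertib,HER2
Capmatinib,c-MET
Dacomitinib,EGFR
Dasatinib,BCR-Abl
Fedratinib,JAK2
Filgotinib,JAK1
Fruquitinib,VEGFR-2
Gefitinib,EGFR
Ibrutinib,BTK
Imatinib,BCR-Abl
Lapatinib,HER2
Lenvatinib,RET
Lenvatinib,VEGFR-2
Mobocertinib,EGFR
Momelotinib,JAK2
Neratinib,HER2
Nilotinib,BCR-Abl
Osimertinib,EGFR
Pacritinib,JAK2
Pazopanib,VEGFR-2
Pirtobrutinib,BTK
Ponatinib,BCR-Abl
Pralsetinib,RET
Regorafenib,VEGFR-2
Ripretinib,PDGFRa
Ruxolitinib,JAK1
Ruxolitinib,JAK2
Savolitinib,c-MET
Selpercatinib,RET
Sorafenib,VEGFR-2
Sunitinib,VEGFR-2
Tepotinib,c-MET
Tivozanib,VEGFR-2
Tucatinib,HER2
Upadacitinib,JAK1
Vandetanib,VEGFR-2
Zanubrutinib,BTK
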