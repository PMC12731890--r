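probe_id,direction,gene_elements,island_relation,enhancer,chromosome,position
cg00041575,EC_HIGH,TSPAN32:Body;C11orf21:TSS1500,OpenSea,FALSE,NA,NA
cg00661485,EC_HIGH,FOXI1:1stExon,Island,FALSE,NA,NA
cg02794695,EC_HIGH,SLA:TSS200;SLA:Body;SLA:5'UTR;TG:Body,OpenSea,FALSE,NA,NA
cg05596756,EC_HIGH,PCED1B:5'UTR;PCED1B:1stExon;PCED1B-AS1:Body,OpenSea,FALSE,NA,NA
cg06183267,EC_HIGH,AFF3:TSS200,OpenSea,FALSE,NA,NA
cg07349094,EC_HIGH,AFF3:1stExon;AFF3:5'UTR,OpenSea,FALSE,NA,NA
cg07380416,EC_HIGH,CD6:5'UTR;CD6:1stExon,OpenSea,FALSE,NA,NA
cg07906724,EC_HIGH,CHRNA6:TSS1500,OpenSea,FALSE,NA,NA
cg08040471,EC_HIGH,CYBC1:5'UTR,N_Shore,FALSE,NA,NA
cg09902130,EC_HIGH,CD6:5'UTR;CD6:1stExon,OpenSea,FALSE,NA,NA
cg10037005,EC_HIGH,CD37:TSS200,N_Shelf,FALSE,NA,NA
cg10590292,EC_HIGH,BIN2:Body,OpenSea,FALSE,NA,NA
cg10861751,EC_HIGH,RGS1:TSS200,OpenSea,FALSE,NA,NA
cg11804789,EC_HIGH,CST7:TSS200,OpenSea,FALSE,NA,NA
cg12177677,EC_HIGH,CYTIP:1stExon,OpenSea,FALSE,NA,NA
cg13821008,EC_HIGH,WIPF1:5'UTR,OpenSea,FALSE,NA,NA
cg14451276,EC_HIGH,AOAH:1stExon;AOAH:5'UTR,OpenSea,FALSE,NA,NA
cg14519350,EC_HIGH,OSM:Body,OpenSea,FALSE,NA,NA
cg15046675,EC_HIGH,CD37:1stExon;CD37:5'UTR,N_Shelf,FALSE,NA,NA
cg15645309,EC_HIGH,BATF:TSS200,OpenSea,FALSE,NA,NA
cg16509569,EC_HIGH,HEM1:1stExon,OpenSea,FALSE,NA,NA
cg16890093,EC_HIGH,PSMB8:TSS1500;TAP1:3'UTR,S_Shore,FALSE,NA,NA
cg16927606,EC_HIGH,IGFLR1:1stExon;IGFLR1:5'UTR,S_Shore,FALSE,NA,NA
cg17771150,EC_HIGH,LCP1:5'UTR,OpenSea,FALSE,NA,NA
cg18384097,EC_HIGH,PTPN7:TSS1500;PTPN7:5'UTR,OpenSea,FALSE,NA,NA
cg18908499,EC_HIGH,GCSAML:TSS1500,OpenSea,FALSE,NA,NA
cg19252956,EC_HIGH,DOCK8:Body,OpenSea,FALSE,NA,NA
cg21614638,EC_HIGH,DAPP1:TSS200,OpenSea,FALSE,NA,NA
cg23093496,EC_HIGH,C16orf54:1stExon;C16orf54:5'UTR,OpenSea,FALSE,NA,NA
cg23612220,EC_HIGH,TNFAIP8L2:5'UTR,OpenSea,FALSE,NA,NA
cg24497819,EC_HIGH,SELPLG:TSS200,OpenSea,FALSE,NA,NA
cg25671438,EC_HIGH,ACAP1:Body,OpenSea,TRUE,NA,NA
cg26158194,EC_HIGH,LSP1:5'UTR;LSP1:1stExon,OpenSea,FALSE,NA,NA
cg26866325,EC_HIGH,PPBPL2:Body,OpenSea,FALSE,NA,NA
cg02254407,LC_HIGH,PLEKHB1:TSS200;PLEKHB1:TSS1500,OpenSea,FALSE,NA,NA
cg02293044,LC_HIGH,GAS2L1:5'UTR,Island,FALSE,NA,NA
cg03171924,LC_HIGH,RUNX3:Body,Island,FALSE,NA,NA
cg04527918,LC_HIGH,UCN:TSS200,Island,FALSE,NA,NA
cg05654164,LC_HIGH,C1orf52:TSS1500,S_Shore,FALSE,NA,NA
cg08578641,LC_HIGH,DNAI1:Body;FAM219A:TSS1500,Island,FALSE,NA,NA
cg13354523,LC_HIGH,CLEC1A:5'UTR;CLEC1A:1stExon,OpenSea,FALSE,NA,NA
cg14440664,LC_HIGH,PDCD1LG2:TSS1500,OpenSea,FALSE,NA,NA
cg15475323,LC_HIGH,MAMSTR:1stExon;MAMSTR:Body;MAMSTR:5'UTR,N_Shelf,FALSE,NA,NA
cg17016000,LC_HIGH,RIN2:TSS1500,OpenSea,FALSE,NA,NA
cg19497444,LC_HIGH,SLC67A1:Body,Island,FALSE,NA,NA
cg24765079,LC_HIGH,CDH1:Body,S_Shore,FALSE,NA,NA
cg26143719,LC_HIGH,C1QTNF6:1stExon,OpenSea,TRUE,NA,NA
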