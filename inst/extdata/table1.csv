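species,order,type,n,area_2000,ratio_full_a2,ratio_nodisp_a2,area_bcs_a2,trend_a2,ratio_full_b2,ratio_nodisp_b2,area_bcs_b2,trend_b2,shift_km,shift_bearing_deg,pct_iucn_covered,pct_pred_in_iucn
Alces alces,Artiodactyla,S,1782,14494,448,85,,W,419,84,,W,288,352,48,98
Capreolus capreolus,Artiodactyla,G,2213,1453,2806,64,,W,2011,72,,W,509,21,51,75
Cervus elaphus,Artiodactyla,G,418,255,1844,79,,W,1329,77,,W,1289,85,27,98
Dama dama,Artiodactyla,G,127,0,,,16819,C,,,4948,C,655,24,,
Odocoileus virginianus,Artiodactyla,G,476,782,424,3,,W,552,32,,W,290,359,,
Sus scrofa,Artiodactyla,G,134,272,16566,99,,W,8130,82,,W,789,6,65,55
Alopex lagopus,Carnivora,S,33,18279,74,57,,L,76,60,,L,154,141,30,50
Canis lupus,Carnivora,G,78,42765,176,85,,W,152,77,,W,513,346,71,93
Gulo gulo,Carnivora,S,53,85503,83,77,,L,93,87,,L,255,106,89,78
Lutra lutra,Carnivora,S,1188,13073,467,98,,W,347,95,,W,336,6,62,93
Lynx lynx,Carnivora,S,109,39056,79,65,,L,92,71,,L,316,318,51,98
Martes martes,Carnivora,S,340,20549,421,96,,W,326,89,,W,294,58,59,95
Meles meles,Carnivora,G,485,4851,1415,100,,W,1162,100,,W,812,32,56,77
Mustela erminea,Carnivora,G,397,64447,100,81,,W,99,80,,L,235,42,72,100
Mustela nivalis,Carnivora,G,476,29127,256,98,,W,212,95,,W,300,34,38,100
Mustela putorius,Carnivora,G,85,323,10386,94,,W,5856,86,,W,688,5,26,87
Neovison vison,Carnivora,S,448,25975,228,86,,W,183,80,,W,206,299,,
Nyctereutes procyonoides,Carnivora,G,170,30955,203,81,,W,190,84,,W,172,352,,
Ursus arctos,Carnivora,S,66,58430,140,92,,W,139,96,,W,580,43,74,95
Vulpes vulpes,Carnivora,G,1951,25908,341,97,,W,289,94,,W,212,96,56,100
Eptesicus nilssonii,Chiroptera,G,1419,370,17873,94,,W,13920,84,,W,1202,36,32,98
Myotis brandtii,Chiroptera,S,294,14,215253,1,,W,144950,76,,W,837,30,19,99
Myotis dasycneme,Chiroptera,S,194,0,,,6,C,,,4,C,1064,59,0,9
Myotis daubentonii,Chiroptera,S,580,0,,,36596,C,,,19968,C,969,50,36,99
Myotis mystacinus,Chiroptera,S,298,35,116117,100,,W,71310,100,,W,639,24,28,56
Myotis nattereri,Chiroptera,G,243,0,,,3524,C,,,1446,C,450,26,20,61
Nyctalus leisleri,Chiroptera,G,193,0,,,3,C,,,2,C,322,2,0,0
Nyctalus noctula,Chiroptera,G,510,0,,,16262,C,,,3386,C,1576,71,24,98
Pipistrellus nathusii,Chiroptera,G,219,0,,,859,C,,,3,C,1014,66,9,75
Pipistrellus pygmaeus,Chiroptera,S,663,0,,,26504,C,,,9416,C,1047,48,47,54
Plecotus auritus,Chiroptera,S,486,15,66541,97,,W,67335,97,,W,462,13,15,98
Vespertilio murinus,Chiroptera,G,359,0,,,7241,C,,,83,C,1001,57,18,98
Erinaceus europaeus,Erinaceomorpha,G,902,10540,819,100,,W,665,100,,W,329,4,62,46
Lepus europaeus,Lagomorpha,G,1427,20067,392,92,,W,329,94,,W,784,306,83,74
Lepus timidus,Lagomorpha,G,1386,50192,188,96,,W,175,94,,W,194,15,70,98
Oryctolagus cuniculus,Lagomorpha,G,214,165,39116,100,,W,22855,100,,W,974,343,,
Apodemus agrarius,Rodentia,G,20,33438,107,89,,W,112,94,,W,138,344,80,65
Apodemus flavicollis,Rodentia,S,159,23650,231,98,,W,182,91,,W,443,353,82,57
Apodemus sylvaticus,Rodentia,G,64,75,31351,78,,W,18580,72,,W,881,100,50,61
Arvicola amphibius,Rodentia,S,196,8697,1004,99,,W,903,99,,W,490,317,49,99
Castor canadensis,Rodentia,S,8,46898,92,81,,L,93,83,,L,1088,253,,
Castor fiber,Rodentia,S,494,10158,551,95,,W,442,92,,W,343,53,58,78
Lemmus lemmus,Rodentia,S,261,14949,10,4,,L,22,13,,L,81,91,27,59
Microtus agrestis,Rodentia,G,205,4351,1468,86,,W,1102,84,,W,512,57,35,98
Micromys minutus,Rodentia,G,86,30369,184,69,,W,153,74,,W,542,339,69,83
Microtus oeconomus,Rodentia,S,88,97964,34,34,,L,61,61,,L,177,110,77,79
Muscardinus avellanarius,Rodentia,S,70,0,,,54,C,,,7,C,802,7,7,82
Mus musculus,Rodentia,G,173,39934,218,96,,W,211,96,,W,105,49,63,100
Myodes glareolus,Rodentia,S,75,52769,163,98,,W,144,95,,W,80,272,74,88
Myodes rufocanus,Rodentia,S,496,63019,50,47,,L,67,64,,L,280,213,60,79
Myopus schisticolor,Rodentia,S,99,72762,121,98,,W,121,99,,W,122,63,94,62
Ondatra zibethicus,Rodentia,S,177,46613,178,87,,W,185,98,,W,533,49,,
Pteromys volans,Rodentia,S,129,15866,61,32,,L,108,51,,W,120,146,40,85
Rattus norvegicus,Rodentia,G,155,26517,252,98,,W,217,96,,W,399,34,50,93
Sciurus vulgaris,Rodentia,S,2043,9839,810,86,,W,626,81,,W,74,208,41,96
Sicista betulina,Rodentia,G,42,47023,167,93,,W,149,93,,W,128,31,91,83
Neomys fodiens,Soricomorpha,S,74,40165,174,90,,W,151,80,,W,279,257,67,84
Sorex araneus,Soricomorpha,G,325,13953,531,95,,W,506,98,,W,68,294,28,100
Sorex minutissimus,Soricomorpha,G,16,71577,124,100,,W,122,99,,W,221,337,88,78
Sorex minutus,Soricomorpha,G,54,25751,329,100,,W,303,100,,W,130,26,57,100
Talpa europaea,Soricomorpha,G,40,10165,466,66,,W,383,87,,W,235,4,37,89
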