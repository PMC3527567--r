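species,trend_a2,variable,area_2000,pct_change_1x,pct_change_2x
Alces alces,W,Annual mean temp.,1189,63,83
Capreolus capreolus,W,Annual mean temp.,4465,22,22
Cervus elaphus,W,Mean temp. driest quarter,373,114,149
Dama dama,C,Mean temp. warmest quarter,4302,1592,2140
Odocoileus virginianus,W,Max. temp. warmest month,5046,-54,-98
Sus scrofa,W,Mean temp. warmest quarter,4302,1592,2140
Alopex lagopus,L,Max. temp. warmest month,34320,-82,-100
Canis lupus,W,Prec. of wettest month,45504,38,-81
Gulo gulo,L,Isothermality,60351,29,43
Lutra lutra,W,Annual mean temp.,4465,19,22
Lynx lynx,L,Prec. driest quarter,40482,62,-96
Martes martes,W,Annual mean temp.,4465,19,22
Meles meles,W,Annual mean temp.,4465,19,22
Mustela erminea,W,Annual mean temp.,4456,1786,-40
Mustela nivalis,W,Annual mean temp.,304,187,323
Mustela putorius,W,Annual mean temp.,16900,5,6
Neovison vison,W,Annual mean temp.,4465,19,22
Nyctereutes procyonoides,W,Max. temp. warmest month,7368,97,127
Ursus arctos,W,Prec. of warmest quarter,72174,3,-96
Vulpes vulpes,W,Annual mean temp.,1189,63,83
Eptesicus nilssonii,W,Annual mean temp.,79,398,144
Myotis brandtii,W,Mean temp. wettest quarter,4030,180,245
Myotis dasycneme,C,Temperature seasonality,79,39733,-100
Myotis daubentonii,C,Annual mean temp.,78,410,1255
Myotis mystacinus,W,Annual mean temp.,79,398,134
Myotis nattereri,C,Annual mean temp.,79,398,192
Nyctalus leisleri,C,Mean temp. driest quarter,79,39733,13807
Nyctalus noctula,C,Annual mean temp.,79,398,158
Pipistrellus nathusii,C,Mean temp. coldest quarter,78,40873,2998
Pipistrellus pygmaeus,C,Annual mean temp.,79,398,150
Plecotus auritus,W,Annual mean temp.,78,410,1253
Vespertilio murinus,C,Annual mean temp.,55910,2,2
Erinaceus europaeus,W,Mean temp. warmest quarter,7436,121,124
Lepus europaeus,W,Mean temp. warmest quarter,55910,2,2
Lepus timidus,W,Annual mean temp.,18840,4,5
Oryctolagus cuniculus,W,Annual mean temp.,304,18580,32210
Apodemus agrarius,W,Max. temp. warmest month,7368,97,127
Apodemus flavicollis,W,Mean temp. warmest quarter,304,187,323
Apodemus sylvaticus,W,Annual mean temp.,18840,4,5
Arvicola amphibius,W,Annual mean temp.,18840,342,417
Castor canadensis,L,Broadleaf woodland,64578,-27,-22
Castor fiber,W,Annual mean temp.,16900,5,6
Lemmus lemmus,L,Mean temp. wettest quarter,39230,-57,-73
Micromys minutus,W,Broadleaf woodland,36273,151,170
Microtus agrestis,W,Annual mean temp.,18840,4,5
Microtus oeconomus,L,Shrub land,98227,0,0
Mus musculus,W,Annual mean temp.,1189,63,83
Muscardinus avellanarius,C,Mean temp. coldest quarter,78,40873,2998
Myodes glareolus,W,Annual mean temp.,16900,5,6
Myodes rufocanus,L,Shrub land,55479,-48,23
Myopus schisticolor,W,Grassland,67099,27,11
Ondatra zibethicus,W,Annual mean temp.,16891,385,-95
Pteromys volans,L,Max. temp. warmest month,36189,127,172
Rattus norvegicus,W,Annual mean temp.,1189,63,83
Sciurus vulgaris,W,Annual mean temp.,4465,19,22
Sicista betulina,W,Mean temp. wettest quarter,42409,7,-68
Neomys fodiens,W,Annual mean temp.,4465,19,22
Sorex araneus,W,Annual mean temp.,16900,445,481
Sorex minutissimus,W,Prec. warmest quarter,97956,-1,-43
Sorex minutus,W,Annual mean temp.,18840,4,5
Talpa europaea,W,Annual mean temp.,18840,342,417
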