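focal,role,partner
Microtus oeconomus,predator,Alopex lagopus
Microtus oeconomus,predator,Gulo gulo
Microtus oeconomus,predator,Vulpes vulpes
Microtus oeconomus,predator,Meles meles
Microtus oeconomus,predator,Martes martes
Microtus oeconomus,predator,Mustela erminea
Microtus oeconomus,predator,Mustela nivalis
Microtus oeconomus,predator,Mustela putorius
Microtus oeconomus,predator,Neovison vison
Microtus oeconomus,predator,Nyctereutes procyonoides
Lepus timidus,competitor,Lepus europaeus
Capreolus capreolus,predator,Canis lupus
Capreolus capreolus,predator,Ursus arctos
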