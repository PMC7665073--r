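diet,ingredient,g_per_100g
Reference,fishmeal,7.46
Reference,n_oculata_defatted,0
Reference,schizochytrium,0
Reference,corn_gluten_meal,30
Reference,soybean_meal,30
Reference,wheat_flour,20
Reference,cah2po4,0.75
Reference,mineral_mix,1
Reference,vitamin_mix,1
Reference,fish_oil,3.2
Reference,lysine_hcl,0
Reference,dl_methionine,0
Reference,cmc,5.07
Reference,choline_chloride,2
33NS,fishmeal,4.69
33NS,n_oculata_defatted,3
33NS,schizochytrium,6.2
33NS,corn_gluten_meal,30
33NS,soybean_meal,30
33NS,wheat_flour,20
33NS,cah2po4,0.75
33NS,mineral_mix,1
33NS,vitamin_mix,1
33NS,fish_oil,0
33NS,lysine_hcl,0.5
33NS,dl_methionine,0.18
33NS,cmc,0.7
33NS,choline_chloride,2
66NS,fishmeal,2.38
66NS,n_oculata_defatted,5.5
66NS,schizochytrium,6.2
66NS,corn_gluten_meal,30
66NS,soybean_meal,30
66NS,wheat_flour,20
66NS,cah2po4,0.75
66NS,mineral_mix,1
66NS,vitamin_mix,1
66NS,fish_oil,0
66NS,lysine_hcl,0.54
66NS,dl_methionine,0.2
66NS,cmc,0.43
66NS,choline_chloride,2
100NS,fishmeal,0
100NS,n_oculata_defatted,8
100NS,schizochytrium,6.2
100NS,corn_gluten_meal,30
100NS,soybean_meal,30
100NS,wheat_flour,20
100NS,cah2po4,0.75
100NS,mineral_mix,1
100NS,vitamin_mix,1
100NS,fish_oil,0
100NS,lysine_hcl,0.6
100NS,dl_methionine,0.2
100NS,cmc,0.27
100NS,choline_chloride,2
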