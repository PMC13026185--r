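class,order,family,taxon,common_name,n,foo,wpoo
Aves,Anseriformes,Anatidae,Spatula_cyanoptera,Cinnamon teal,2,0.05,0.05
Aves,Gruiformes,Rallidae,Aramides_axillaris,Rufous-necked wood rail,5,0.12,0.08
Aves,Gruiformes,Rallidae,Gallinula_chloropus,Common moorhen,4,0.10,0.10
Aves,Gruiformes,Rallidae,Rallus_longirostris,Mangrove rail,8,0.20,0.12
Aves,Pelecaniformes,Threskiornithidae,Platalea_ajaja,Roseate spoonbill,1,0.02,0.02
Aves,Passeriformes,Tachurididae,Tachuris_rubrigastra,Many-colored rush-tyrant,4,0.10,0.07
Mammalia,Rodentia,Cricetidae,Aegialomys_xanthaeolus,Yellowish rice rat,24,0.59,0.53
Mammalia,Rodentia,Muridae,Mus_musculus,House mouse,2,0.05,0.02
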