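family,genus,species,pair,range_class,n_trees,eoo_km2
Annonaceae,Guatteria,Guatteria amplifolia,P01,widespread,10,1.02e6
Annonaceae,Guatteria,Guatteria pudica,P01,endemic,16,6.87e2
Annonaceae,Guatteria,Guatteria rostrata,P02,widespread,10,6.45e4
Annonaceae,Guatteria,Guatteria chiriquiensis,P02,endemic,9,8.60e3
Annonaceae,Unonopsis,Unonopsis theobromifolia,P03,widespread,10,2.81e4
Annonaceae,Unonopsis,Unonopsis osae,P03,endemic,10,7.54e2
Araliaceae,Dendropanax,Dendropanax arboreus,P04,widespread,10,7.69e6
Araliaceae,Dendropanax,Dendropanax ravenii,P04,endemic,10,1.96e3
Boraginaceae,Cordia,Cordia cymosa,P05,widespread,8,3.66e5
Boraginaceae,Cordia,Cordia liesneri,P05,endemic,9,4.07e3
Burseraceae,Protium,Protium panamense,P06,widespread,8,1.98e5
Burseraceae,Protium,Protium pecuniosum,P06,endemic,10,1.48e3
Clusiaceae,Chrysochlamys,Chrysochlamys glauca,P07,widespread,10,3.79e5
Clusiaceae,Chrysochlamys,Chrysochlamys skutchii,P07,endemic,9,2.38e4
Clusiaceae,Garcinia,Garcinia magnifolia,P08,widespread,10,1.64e5
Clusiaceae,Garcinia,Garcinia aguilari,P08,endemic,10,9.43e1
Euphorbiaceae,Sapium,Sapium glandulosum,P09,widespread,10,1.35e7
Euphorbiaceae,Sapium,Sapium allenii,P09,endemic,11,8.89e2
Fabaceae,Inga,Inga spectabilis,P10,widespread,9,2.51e6
Fabaceae,Inga,Inga skutchii,P10,endemic,10,7.79e3
Lauraceae,Ocotea,Ocotea mollifolia,P11,widespread,10,1.14e5
Lauraceae,Ocotea,Ocotea rivularis,P11,endemic,9,6.68e2
Melastomataceae,Miconia,Miconia donaeana,P12,widespread,10,1.22e6
Melastomataceae,Miconia,Miconia dissitinervia,P12,endemic,11,3.75e3
Melastomataceae,Miconia,Miconia trinervia,P13,widespread,10,5.89e6
Melastomataceae,Miconia,Miconia osaensis,P13,endemic,10,9.61e1
Primulaceae,Ardisia,Ardisia compressa,P14,widespread,9,1.44e6
Primulaceae,Ardisia,Ardisia dunlapiana,P14,endemic,10,1.44e3
Rubiaceae,Faramea,Faramea occidentalis,P15,widespread,11,1.18e7
Rubiaceae,Faramea,Faramea permagnifolia,P15,endemic,12,5.38e1
Sapotaceae,Pouteria,Pouteria subrotata,P16,widespread,8,1.72e6
Sapotaceae,Pouteria,Pouteria lecythidicarpa,P16,endemic,10,1.33e4
Sapotaceae,Pouteria,Pouteria torta,P17,widespread,10,1.08e7
Sapotaceae,Pouteria,Pouteria triplarifolia,P17,endemic,6,2.41e3
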