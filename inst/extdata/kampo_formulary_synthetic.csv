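product_name,full_daily_dose_g,scutellariae_radix,bupleuri_radix,pinelliae_tuber,other_crude_g
Shosaikoto,7.5,3,7,5,9
Saireito,9,3,7,5,12
Saikokaryukotsuboreito,7.5,2.5,5,4,10
Saibokuto,7.5,3,7,5,11
Bofutsushosan,7.5,2,0,0,15
Orengedokuto,7.5,3,0,0,6
Seishinrenshiin,7.5,3,0,0,10
Otsujito,7.5,3,5,0,8
Saikokeishikankyoto,7.5,3,6,0,9
Hangeshashinto,7.5,2.5,0,5,8
Nijutsuto,7.5,3,0,4,11
Yokukansan,7.5,0,2,0,10
Kamishoyosan,7.5,0,3,0,10
Hochuekkito,7.5,0,2,0,12
Bakumondoto,9,0,0,5,12
Rikkunshito,7.5,0,0,4,10
Shoseiryuto,9,0,0,6,11
Yokukansankachimpihange,7.5,0,2,5,10
Kakkonto,7.5,0,0,0,12
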