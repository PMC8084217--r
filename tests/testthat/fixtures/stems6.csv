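site_id,plot_id,stage,group,dbh_cm,height_m,alive,grazing_damage
grazed,p1,adult,broadleaf,25.2,,TRUE,FALSE
grazed,p1,sapling,broadleaf,2.1,1.4,TRUE,FALSE
grazed,p2,sapling,broadleaf,4.0,2.8,TRUE,FALSE
grazed,p1,adult,motacu,36.0,14.2,TRUE,FALSE
grazed,p2,sapling,motacu,,2.0,TRUE,FALSE
grazed,p2,adult,other_palm,40.5,,TRUE,FALSE
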