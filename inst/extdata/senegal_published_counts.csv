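list_name,all,hopital,centre_de_sante,poste_de_sante,case_de_sante
consolidated_facility_list,4685,81,257,2349,1998
spa_2012_2013_frame,3084,86,242,1250,1506
spa_2017_frame,3764,68,148,1853,1695
spa_2019_frame,3967,80,153,1859,1875
health_map_2021_public,3964,40,110,1531,2283
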