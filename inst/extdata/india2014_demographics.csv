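region_id,base_year,crude_birth_rate,growth_rate,prev_whz_lt_m3,prev_whz_lt_m2,prev_waz_lt_m3,frac_women_govt,malaria_endemic,pop_m_0_5,pop_m_5_10,pop_m_10_15,pop_m_15_20,pop_m_20_25,pop_m_25_30,pop_m_30_35,pop_m_35_40,pop_m_40_45,pop_m_45_50,pop_m_50_55,pop_m_55_60,pop_m_60_65,pop_m_65_70,pop_m_70_75,pop_m_75_80,pop_m_80_85,pop_m_85_90,pop_m_90_95,pop_m_95_100,pop_f_0_5,pop_f_5_10,pop_f_10_15,pop_f_15_20,pop_f_20_25,pop_f_25_30,pop_f_30_35,pop_f_35_40,pop_f_40_45,pop_f_45_50,pop_f_50_55,pop_f_55_60,pop_f_60_65,pop_f_65_70,pop_f_70_75,pop_f_75_80,pop_f_80_85,pop_f_85_90,pop_f_90_95,pop_f_95_100
India,2011,22.099,0.017449,0.064,0.197,0.0786,0.00327,0,57753600,64972800,67942400,61696000,59596800,54425600,48128000,43622400,36300800,30976000,24576000,19865600,17664000,12544000,9216000,4915200,3072000,1484800,614400,614400,55046400,61927200,64757600,58804000,56803200,51874400,45872000,41577600,34599200,29524000,23424000,18934400,16836000,11956000,8784000,4684800,2928000,1415200,585600,585600
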