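plant,total_cod,total_cod_sd,soluble_cod,soluble_cod_sd,cod_100kda_045um,cod_100kda_045um_sd,cod_10_100kda,cod_10_100kda_sd,cod_1_10kda,cod_1_10kda_sd,cod_lt_1kda,cod_lt_1kda_sd,tss,tss_sd,tn,tn_sd,nh4_n,nh4_n_sd,tp,tp_sd,po4_p,po4_p_sd,vfa_cod,vfa_cod_sd
Utrecht,605,9,175,1,11,2,42,2,17,2,106,1,260,1,61.7,1.4,45.9,0.2,8.0,0.2,4.6,0.1,30.8,0.7
Harnaschpolder,456,20,105,1,21.6,0.2,9.5,0.8,19.8,1.1,67.2,0.8,221,8,49.0,0.6,33.8,0.5,6.22,0.03,3.39,0.03,17.7,0.4
Bath,649,44,248,1,23,4,10,4,45,2,170,1,268,12,59.0,1.7,42.2,0.6,10.97,0.06,7.47,0.15,36.3,0.2
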