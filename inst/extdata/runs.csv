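"run_id","source_quality","mean_energy_keV","geometry","zenith_angle_deg","dose_rate_mGy_h","duration_s","n_rotations","reference_distance_m","purpose"
"CAL_Cs137_AP","Cs-137",662,"AP",,10.5,720,,3.5,"calibration"
"N150_AP","N-150",119,"AP",,27.6,315,,3.38,"phantom"
"N150_ROT030","N-150",119,"ROT",30,25.7,180,4,3.5,"phantom"
"N150_ROT060","N-150",119,"ROT",60,25.7,180,4,3.5,"phantom"
"N150_ROT090","N-150",119,"ROT",90,25.7,180,4,3.5,"phantom"
"N150_ROT120","N-150",119,"ROT",120,25.7,180,4,3.5,"phantom"
"N150_ROT150","N-150",119,"ROT",150,25.7,180,4,3.5,"phantom"
"N250_AP","N-250",207,"AP",,7.88,990,,3.38,"phantom"
"N250_ROT030","N-250",207,"ROT",30,7.33,445,11,3.5,"phantom"
"N250_ROT060","N-250",207,"ROT",60,7.33,445,11,3.5,"phantom"
"N250_ROT090","N-250",207,"ROT",90,7.33,445,11,3.5,"phantom"
"N250_ROT120","N-250",207,"ROT",120,7.33,445,11,3.5,"phantom"
"N250_ROT150","N-250",207,"ROT",150,7.33,445,11,3.5,"phantom"
"Cs137_AP","Cs-137",662,"AP",,11.3,720,,3.38,"phantom"
"Cs137_ROT030","Cs-137",662,"ROT",30,10.5,360,8,3.5,"phantom"
"Cs137_ROT060","Cs-137",662,"ROT",60,10.5,360,8,3.5,"phantom"
"Cs137_ROT090","Cs-137",662,"ROT",90,10.5,360,8,3.5,"phantom"
"Cs137_ROT120","Cs-137",662,"ROT",120,10.5,360,8,3.5,"phantom"
"Cs137_ROT150","Cs-137",662,"ROT",150,10.5,360,8,3.5,"phantom"
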