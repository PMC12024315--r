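patient_id,sex,aortic_regurgitation,height_cm,weight_kg,bsa_m2,age_years,reference_valve_size,peak_systolic_flow_mls,mmi_g_m2,lvef_pct,ntprobnp_ng_l
1,F,no,164,68,1.8,69,23,354,50,69,247
2,M,mild,192,95,2.3,62,27,430,55,53,170
3,M,no,185,98,2.3,72,25,394,64,52,210
4,M,moderate,198,105,2.4,64,23,539,73,57,366
5,M,no,180,81,2.1,60,23,367,71,63,96
6,F,moderate,168,68,1.8,64,23,235,44,54,197
7,M,no,184,100,2.3,70,23,407,46,61,335
8,F,mild,170,70,1.9,57,21,296,47,64,516
9,M,no,169,88,2.1,68,25,412,62,54,250
10,M,no,190,110,2.4,59,25,464,59,54,63
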