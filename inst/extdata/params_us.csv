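name,country,category,base,low,high,dist,units,source
cost_ibrutinib,us,drug_cost,879.20,703.36,1055.04,gamma,USD per day on 560 mg daily dose,wholesale acquisition cost
cost_venetoclax,us,drug_cost,26.00,20.8,31.2,gamma,USD per 20 mg tablet,wholesale acquisition cost
cost_rituximab,us,drug_cost,940.00,752,1128,gamma,USD per 100 mg vial,wholesale acquisition cost
cost_bendamustine,us,drug_cost,2375.19,1900.08,2850.12,gamma,USD per 70 mg vial,wholesale acquisition cost
mgmt_pfs,us,management_cost,1696.85,1357.48,2036.22,gamma,USD per cycle in PFS state,literature
mgmt_pd,us,management_cost,8435.78,6748.62,10122.94,gamma,USD per cycle in PD state,literature
cost_pet_ct,us,one_off_cost,5828.84,4663.07,6994.61,gamma,USD per scan,literature
cost_end_of_life,us,one_off_cost,28163.46,22530.77,33796.15,gamma,USD per death,literature
cost_ae_anemia,us,ae_cost,8234.58,6587.66,9881.50,gamma,USD per event,literature
cost_ae_neutropenia,us,ae_cost,12176.13,9740.90,14611.36,gamma,USD per event,literature
cost_ae_pneumonia,us,ae_cost,20113.76,16091.01,24136.51,gamma,USD per event,literature
cost_ae_thrombocytopenia,us,ae_cost,1437.80,1150.24,1725.36,gamma,USD per event,literature
cost_ae_leukopenia,us,ae_cost,216.48,173.18,259.78,gamma,USD per event,literature
cost_ae_atrial_fibrillation,us,ae_cost,22541.81,18033.45,27050.17,gamma,USD per event,literature
bsa,us,bsa,1.96,1.57,2.35,gamma,m2,literature
discount,us,discount,0.03,0,0.08,fixed,fraction per year,national guideline
wtp,us,threshold,150000,NA,NA,fixed,USD per QALY,conventional threshold
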