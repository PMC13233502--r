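name,country,category,base,low,high,dist,units,source
cost_ibrutinib,china,drug_cost,22.07,17.66,26.48,gamma,USD per day on 560 mg daily dose,2024 average winning bid price
cost_venetoclax,china,drug_cost,38.46,30.77,46.15,gamma,USD per 100 mg tablet,2024 average winning bid price
cost_rituximab,china,drug_cost,179.79,143.83,215.75,gamma,USD per 100 mg vial,2024 average winning bid price
cost_bendamustine,china,drug_cost,59.35,47.48,71.22,gamma,USD per 25 mg vial,2024 average winning bid price
mgmt_y0_2,china,management_cost,76.76,61.41,92.11,gamma,USD per cycle (years 0-2 since entry),literature
mgmt_y3_5,china,management_cost,44.63,35.70,53.56,gamma,USD per cycle (years 3-5 since entry),literature
mgmt_y6_plus,china,management_cost,27.67,22.14,33.20,gamma,USD per cycle (years 6+ since entry),literature
cost_pet_ct,china,one_off_cost,736.52,589.22,883.82,gamma,USD per scan,literature
cost_end_of_life,china,one_off_cost,5289.31,4231.45,6347.17,gamma,USD per death,literature
cost_ae_anemia,china,ae_cost,506.52,405.22,607.82,gamma,USD per event,literature
cost_ae_neutropenia,china,ae_cost,99.30,79.44,119.16,gamma,USD per event,literature
cost_ae_pneumonia,china,ae_cost,1041.34,833.07,1249.61,gamma,USD per event,literature
cost_ae_thrombocytopenia,china,ae_cost,161.41,129.13,193.69,gamma,USD per event,literature
cost_ae_leukopenia,china,ae_cost,220.37,176.30,264.44,gamma,USD per event,literature
cost_ae_atrial_fibrillation,china,ae_cost,645.75,516.60,774.90,gamma,USD per event,literature
bsa,china,bsa,1.72,1.38,2.06,gamma,m2,literature
discount,china,discount,0.05,0,0.08,fixed,fraction per year,national guideline
wtp,china,threshold,40334,NA,NA,fixed,USD per QALY,3x 2024 per-capita GDP
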