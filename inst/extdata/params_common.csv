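name,country,category,base,low,high,dist,units,source
os_ven_meanlog,both,survival,3.827,NA,NA,fixed,log-months,model fitting (log-normal OS ibrutinib+venetoclax)
os_ven_sdlog,both,survival,1.727,NA,NA,fixed,log-months,model fitting (log-normal OS ibrutinib+venetoclax)
pfs_ven_meanlog,both,survival,3.501,NA,NA,fixed,log-months,model fitting (log-normal PFS ibrutinib+venetoclax)
pfs_ven_sdlog,both,survival,1.598,NA,NA,fixed,log-months,model fitting (log-normal PFS ibrutinib+venetoclax)
os_pbo_shape,both,survival,1.012,NA,NA,fixed,dimensionless,model fitting (log-logistic OS ibrutinib+placebo)
os_pbo_scale,both,survival,38.350,NA,NA,fixed,months,model fitting (log-logistic OS ibrutinib+placebo)
pfs_pbo_meanlog,both,survival,2.960,NA,NA,fixed,log-months,model fitting (log-normal PFS ibrutinib+placebo)
pfs_pbo_sdlog,both,survival,1.512,NA,NA,fixed,log-months,model fitting (log-normal PFS ibrutinib+placebo)
risk_anemia_ven,both,ae_risk,0.10,0.08,0.12,beta,probability,trial grade >=3 AE incidence
risk_neutropenia_ven,both,ae_risk,0.31,0.25,0.37,beta,probability,trial grade >=3 AE incidence
risk_pneumonia_ven,both,ae_risk,0.11,0.09,0.13,beta,probability,trial grade >=3 AE incidence
risk_thrombocytopenia_ven,both,ae_risk,0.13,0.10,0.16,beta,probability,trial grade >=3 AE incidence
risk_leukopenia_ven,both,ae_risk,0.07,0.06,0.08,beta,probability,trial grade >=3 AE incidence
risk_atrial_fibrillation_ven,both,ae_risk,0.05,0.04,0.06,beta,probability,trial grade >=3 AE incidence
risk_anemia_pbo,both,ae_risk,0.03,0.02,0.04,beta,probability,trial grade >=3 AE incidence
risk_neutropenia_pbo,both,ae_risk,0.11,0.09,0.13,beta,probability,trial grade >=3 AE incidence
risk_pneumonia_pbo,both,ae_risk,0.12,0.10,0.14,beta,probability,trial grade >=3 AE incidence
risk_thrombocytopenia_pbo,both,ae_risk,0.08,0.06,0.10,beta,probability,trial grade >=3 AE incidence
risk_leukopenia_pbo,both,ae_risk,0,NA,NA,fixed,probability,trial grade >=3 AE incidence (zero events)
risk_atrial_fibrillation_pbo,both,ae_risk,0.05,0.04,0.06,beta,probability,trial grade >=3 AE incidence
subsequent_ven,both,proportion,0.31,0.25,0.37,beta,fraction,trial subsequent-therapy uptake
subsequent_pbo,both,proportion,0.45,0.36,0.54,beta,fraction,trial subsequent-therapy uptake
u_pfs_ven,both,utility,0.827,0.755,0.86,beta,utility,trial EQ-5D-5L
u_pfs_pbo,both,utility,0.824,0.767,0.867,beta,utility,trial EQ-5D-5L
u_pd,both,utility,0.68,0.634,0.727,beta,utility,literature
du_anemia,both,disutility,0.007,0.006,0.008,beta,utility decrement,literature
du_neutropenia,both,disutility,0.032,0.026,0.038,beta,utility decrement,literature
du_pneumonia,both,disutility,0.150,0.120,0.180,beta,utility decrement,literature
du_thrombocytopenia,both,disutility,0.038,0.030,0.046,beta,utility decrement,literature
du_leukopenia,both,disutility,0.010,0.008,0.012,beta,utility decrement,literature
du_atrial_fibrillation,both,disutility,0.150,0.120,0.180,beta,utility decrement,literature
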