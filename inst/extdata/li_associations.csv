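"disease_name","or_per_sd","ci_lower","ci_upper","direction","source","significant"
"Thyroid cancer",2.83,NA,NA,"per_sd_longer","Li 2020",TRUE
"Lymphomas and multiple myeloma",1.66,NA,NA,"per_sd_longer","Li 2020",TRUE
"Uterine fibroid",1.66,NA,NA,"per_sd_longer","Li 2020",TRUE
"Benign prostatic hyperplasia",1.46,NA,NA,"per_sd_longer","Li 2020",TRUE
"Leukemia",2.01,NA,NA,"per_sd_longer","Li 2020",TRUE
"Lung cancer",1.81,NA,NA,"per_sd_longer","Li 2020",TRUE
"Skin cancer (including melanoma)",1.45,NA,NA,"per_sd_longer","Li 2020",TRUE
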