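{
  "panel": {
    "rsid": ["rs1052990", "rs11656696", "rs59072263", "rs2472493", "rs58073046", "rs2286885", "rs6445055", "rs8176743", "rs747782"],
    "risk_allele": ["T", "C", "G", "C", "G", "T", "G", "A", "G"],
    "locus": ["CAV2", "GAS7", "GLCCI1/ICA1", "ABCA1", "ARHGEF12", "FAM125B", "FNDC3B", "ABO", "PTPRJ"],
    "risk_allele_freq": [0.4847, 0.4847, 0.4847, 0.4847, 0.4847, 0.4847, 0.4847, 0.4847, 0.4847],
    "iop_effect_mmHg": [0.205, 0.205, 0.205, 0.205, 0.205, 0.205, 0.205, 0.205, 0.205]
  },
  "baseline_iop_mmHg": 13.26,
  "age_effect_mmHg": -0.03,
  "age_reference_years": 65,
  "male_effect_mmHg": 0.8,
  "iop_noise": {
    "family": "gaussian",
    "sd": 2.72
  },
  "glaucoma_iop_offset_mmHg": 4.62,
  "htg_tail": {
    "family": "lognormal",
    "meanlog": 0.957,
    "sdlog": 1.142,
    "threshold_mmHg": 22
  },
  "vulnerability_prevalence": 0.5,
  "vcdr_model": {
    "intercept": 0.345,
    "iop_slope": 0.002,
    "glaucoma_offset": 0.45,
    "noise_sd": 0.14
  },
  "groups": {
    "group": ["control", "NTG", "HTG"],
    "n": [246, 261, 255],
    "age_mean": [67.7, 63.8, 63.7],
    "age_sd": [11.2, 13.3, 14.2],
    "male_fraction": [0.366, 0.391, 0.612]
  },
  "max_attempts_factor": 1000
}
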