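{
  "snps": [
    {"name": "10q26-rs2981582",  "gene": "FGFR2",         "other_allele": "C", "risk_allele": "T", "risk_allele_freq": 0.38, "or_per_allele": 1.22},
    {"name": "8q24-rs13281615",  "gene": "intergenic",    "other_allele": "A", "risk_allele": "G", "risk_allele_freq": 0.41, "or_per_allele": 1.12},
    {"name": "11p15-rs3817198",  "gene": "LSP1",          "other_allele": "T", "risk_allele": "C", "risk_allele_freq": 0.31, "or_per_allele": 1.08},
    {"name": "5q11-rs889312",    "gene": "MAP3K1",        "other_allele": "A", "risk_allele": "C", "risk_allele_freq": 0.28, "or_per_allele": 1.11},
    {"name": "16q12-rs3803662",  "gene": "TOX3/TNRC9",    "other_allele": "C", "risk_allele": "T", "risk_allele_freq": 0.26, "or_per_allele": 1.23},
    {"name": "2q35-rs13387042",  "gene": "intergenic",    "other_allele": "G", "risk_allele": "A", "risk_allele_freq": 0.52, "or_per_allele": 1.14},
    {"name": "5p12-rs10941679",  "gene": "MRPS30",        "other_allele": "A", "risk_allele": "G", "risk_allele_freq": 0.26, "or_per_allele": 1.12},
    {"name": "17q23-rs6504950",  "gene": "COX11/STXBP4",  "other_allele": "G", "risk_allele": "A", "risk_allele_freq": 0.28, "or_per_allele": 0.95},
    {"name": "3p24-rs4973768",   "gene": "SLC4A7/NEK10",  "other_allele": "C", "risk_allele": "T", "risk_allele_freq": 0.46, "or_per_allele": 1.11},
    {"name": "2q33-rs17468277",  "gene": "CASP8",         "other_allele": "C", "risk_allele": "T", "risk_allele_freq": 0.13, "or_per_allele": 0.94},
    {"name": "19q13-rs1982073",  "gene": "TGFB1",         "other_allele": "T", "risk_allele": "C", "risk_allele_freq": 0.38, "or_per_allele": 1.04},
    {"name": "6q25-rs3020314",   "gene": "ESR1",          "other_allele": "T", "risk_allele": "C", "risk_allele_freq": 0.32, "or_per_allele": 1.03}
  ]
}
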