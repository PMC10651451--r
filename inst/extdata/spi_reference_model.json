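{
  "model": "spi_linear",
  "response": "SPI (g/L GAE)",
  "ncomp": 3,
  "intercept": 2.4385,
  "coefficients": {
    "volatile_acidity": 1.5492,
    "tartaric_acid": 0.3903,
    "titratable_acidity": 0.1844,
    "abs_520nm": 0.1102,
    "procyanidin_B1": 0.0329,
    "buffer_capacity": 0.0145,
    "catechin_terminal": 0.0068,
    "epigallocatechin_gallate_phl": 0.002,
    "vanillin_assay": 0.0004,
    "catechin_epicatechin_phl": 0.0003,
    "proanthocyanidin_assay": 0.0002,
    "tannin_fe": 0.0001,
    "epigallocatechin_phl": -0.0016,
    "polysaccharides": -0.0017,
    "total_aldehydes": -0.0101,
    "protein_content": -0.0101,
    "epicatechin_terminal": -0.0221,
    "tannin_fe_anthocyanin": -0.0337,
    "pH": -0.7919
  },
  "units": {
    "volatile_acidity": "g acetic acid/L",
    "tartaric_acid": "g/L",
    "titratable_acidity": "g tartaric acid/L",
    "abs_520nm": "AU",
    "procyanidin_B1": "mg/L",
    "buffer_capacity": "meq/pH unit",
    "catechin_terminal": "mg/L",
    "epigallocatechin_gallate_phl": "mg/L",
    "vanillin_assay": "mg (+)-catechin/L",
    "catechin_epicatechin_phl": "mg/L",
    "proanthocyanidin_assay": "mg cyanidin chloride/L",
    "tannin_fe": "mg/L",
    "epigallocatechin_phl": "mg/L",
    "polysaccharides": "mg/L",
    "total_aldehydes": "mg/L",
    "protein_content": "mg/L",
    "epicatechin_terminal": "mg/L",
    "tannin_fe_anthocyanin": "ratio",
    "pH": "pH units"
  }
}
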