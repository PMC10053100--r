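{
  "_comment": [
    "Demo configuration for urban-park surface soils, central China.",
    "Background (ABV) and guide values follow the Hubei provincial background",
    "and the GB15618-2018 agricultural-land risk screening values; MDLs are",
    "ICP-MS method detection limits. Toxicity (RfD, SF) and exposure entries",
    "are EPA-conventional stand-in defaults widely used in Chinese urban-soil",
    "risk studies -- edit them to match a specific assessment. mn_background",
    "(583 mg/kg) is a SYNTHETIC stand-in taken from the Chinese national soil",
    "Mn background; supply the regional value for real work.",
    "Units: concentrations mg/kg; RfD mg/(kg d); SF 1/(mg/(kg d));",
    "IngR mg/d; InhR m3/d; EFreq d/a; ED a; BW kg; AT d; SA cm2;",
    "AF mg/(cm2 d); ABS unitless; PEF m3/kg."
  ],
  "reference": {
    "mn_background": 583,
    "metals": {
      "Cd": {"background": 0.17, "guide": 0.60,  "mdl": 0.09},
      "Cr": {"background": 86,   "guide": 250,   "mdl": 2},
      "Cu": {"background": 30.7, "guide": 100,   "mdl": 0.6},
      "Zn": {"background": 83.6, "guide": 300,   "mdl": 1},
      "Ni": {"background": 37.3, "guide": 190,   "mdl": 1},
      "Pb": {"background": 26.7, "guide": 170,   "mdl": 2}
    }
  },
  "toxicity": {
    "rfd": {
      "Cd": {"ingestion": 1e-3,  "dermal": 1e-5,    "inhalation": 1e-3},
      "Cr": {"ingestion": 3e-3,  "dermal": 6e-5,    "inhalation": 2.86e-5},
      "Cu": {"ingestion": 4e-2,  "dermal": 1.2e-2,  "inhalation": 4.02e-2},
      "Zn": {"ingestion": 0.3,   "dermal": 6e-2,    "inhalation": 0.3},
      "Ni": {"ingestion": 2e-2,  "dermal": 5.4e-3,  "inhalation": 2.06e-2},
      "Pb": {"ingestion": 3.5e-3, "dermal": 5.25e-4, "inhalation": 3.52e-3}
    },
    "sf": {
      "Cd": {"ingestion": 6.1,    "inhalation": 6.3},
      "Cr": {"ingestion": 0.5,    "inhalation": 42},
      "Ni": {"inhalation": 0.84},
      "Pb": {"ingestion": 8.5e-3}
    }
  },
  "exposure": {
    "adult": {
      "IngR":  {"family": "triangular", "min": 50, "mode": 100, "max": 200},
      "InhR":  14.5,
      "EFreq": {"family": "triangular", "min": 180, "mode": 350, "max": 365},
      "ED":    24,
      "BW":    {"family": "normal", "mean": 70, "sd": 10, "trunc_min": 40, "trunc_max": 110},
      "AT_nc": 8760,
      "AT_ca": 25550,
      "SA":    5700,
      "AF":    0.07,
      "ABS":   0.001,
      "PEF":   1.36e9
    },
    "child": {
      "IngR":  {"family": "triangular", "min": 100, "mode": 200, "max": 300},
      "InhR":  7.5,
      "EFreq": {"family": "triangular", "min": 180, "mode": 350, "max": 365},
      "ED":    6,
      "BW":    {"family": "normal", "mean": 15, "sd": 2, "trunc_min": 8, "trunc_max": 30},
      "AT_nc": 2190,
      "AT_ca": 25550,
      "SA":    2800,
      "AF":    0.2,
      "ABS":   0.001,
      "PEF":   1.36e9
    }
  },
  "error_fraction": 0.1,
  "ef_class_bounds": [2, 5, 20, 40]
}
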