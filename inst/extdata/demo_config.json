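{
  "seed": 1,
  "outdir": "out",
  "simulate": {
    "n_loci": 60,
    "genome": {
      "arm": ["chr2R", "chr3L", "chr3R", "chrX"],
      "length": [900000, 900000, 900000, 900000]
    }
  },
  "window_sizes": [10000, 4000],
  "n_samples": 2000,
  "class_map": {
    "CHRIZ": "active", "RNApolII": "active", "BEAF-32": "active",
    "WDS": "active", "ORC2": "active", "TRX": "active",
    "PC": "silent", "E(Z)": "silent", "dRING": "silent",
    "SU(HW)": "silent", "MOD(MDG4)": "silent", "CTCF": "silent"
  }
}
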