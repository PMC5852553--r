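{
  "simulate": {
    "seed": 20180124,
    "n_birds": 400,
    "n_snps": 10000,
    "n_divergent": 5,
    "delta_p_planted": 0.8,
    "mean_coverage": 20,
    "n_validation": 779,
    "n_val_males": 345,
    "val_n_snps": 191
  },
  "screen": {},
  "window": 50000,
  "n_extreme": 48,
  "n_pools": 3,
  "pool_size": 16,
  "sex_balanced": false,
  "h2": null,
  "qpcr_reference_group": "HRFI"
}
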