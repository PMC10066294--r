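{
  "name": "nsclc",
  "N_0": 0,
  "N_eval": 20,
  "N_adapt": 30,
  "dose_grid": [1.5, 4, 0.1],
  "alpha_beta_tumor": 10,
  "alpha_beta_oar": 3,
  "D_T_tumor": 20,
  "D_T_oar": 6,
  "D_max": 4,
  "lql_mode": "continuous",
  "goal_tiers": [
    {
      "tcp_min": 0.7,
      "ntcp_max": 0.172,
      "bonus": 2
    },
    {
      "tcp_min": 0.5,
      "ntcp_max": 0.5,
      "bonus": 1
    }
  ],
  "features": [
    {
      "name": "tumor_geud",
      "kind": "continuous",
      "unit": "Gy",
      "role": "dosimetric-tumor"
    },
    {
      "name": "oar_geud",
      "kind": "continuous",
      "unit": "Gy",
      "role": "dosimetric-oar"
    },
    {
      "name": "age",
      "kind": "continuous",
      "unit": "years",
      "role": "covariate"
    },
    {
      "name": "sex",
      "kind": "binary",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "ecog_ps",
      "kind": "categorical",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "biomarker_a",
      "kind": "continuous",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "biomarker_b",
      "kind": "continuous",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "biomarker_c",
      "kind": "continuous",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "snp_a",
      "kind": "categorical",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "snp_b",
      "kind": "categorical",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "snp_c",
      "kind": "categorical",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "mirna_a",
      "kind": "continuous",
      "unit": "",
      "role": "covariate"
    },
    {
      "name": "mirna_b",
      "kind": "continuous",
      "unit": "",
      "role": "covariate"
    }
  ]
}
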