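{
  "nodes": ["tumor_geud", "oar_geud", "age", "sex", "ecog_ps", "biomarker_a", "biomarker_b", "biomarker_c", "snp_a", "snp_b", "snp_c", "mirna_a", "mirna_b"],
  "edges": [
    {
      "covs": "age",
      "2": "sex"
    },
    {
      "covs": "sex",
      "2": "ecog_ps"
    },
    {
      "covs": "ecog_ps",
      "2": "biomarker_a"
    },
    {
      "covs": "biomarker_a",
      "2": "biomarker_b"
    },
    {
      "covs": "biomarker_b",
      "2": "biomarker_c"
    },
    {
      "covs": "biomarker_c",
      "2": "snp_a"
    },
    {
      "covs": "snp_a",
      "2": "snp_b"
    },
    {
      "covs": "snp_b",
      "2": "snp_c"
    },
    {
      "covs": "snp_c",
      "2": "mirna_a"
    },
    {
      "covs": "mirna_a",
      "2": "mirna_b"
    },
    {
      "covs": "age",
      "2": "tumor_geud"
    },
    {
      "covs": "sex",
      "2": "oar_geud"
    },
    {
      "covs": "ecog_ps",
      "2": "tumor_geud"
    },
    {
      "covs": "biomarker_a",
      "2": "oar_geud"
    },
    {
      "covs": "biomarker_b",
      "2": "tumor_geud"
    },
    {
      "covs": "biomarker_c",
      "2": "oar_geud"
    },
    {
      "covs": "snp_a",
      "2": "tumor_geud"
    },
    {
      "covs": "snp_b",
      "2": "oar_geud"
    },
    {
      "covs": "snp_c",
      "2": "tumor_geud"
    },
    {
      "covs": "mirna_a",
      "2": "oar_geud"
    },
    {
      "covs": "mirna_b",
      "2": "tumor_geud"
    }
  ]
}
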