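{
  "signature_name": "oncotype_dx_target_genes",
  "genes": [
    {"symbol": "GRB7",   "role": "grb7"},
    {"symbol": "ERBB2",  "role": "grb7"},
    {"symbol": "ESR1",   "role": "er"},
    {"symbol": "PGR",    "role": "er"},
    {"symbol": "BCL2",   "role": "er"},
    {"symbol": "SCUBE2", "role": "er"},
    {"symbol": "BIRC5",  "role": "proliferation"},
    {"symbol": "MKI67",  "role": "proliferation"},
    {"symbol": "MYBL2",  "role": "proliferation"},
    {"symbol": "CCNB1",  "role": "proliferation"},
    {"symbol": "AURKA",  "role": "proliferation"},
    {"symbol": "CTSL2",  "role": "invasion"},
    {"symbol": "MMP11",  "role": "invasion"},
    {"symbol": "CD68",   "role": "cd68"},
    {"symbol": "GSTM1",  "role": "gstm1"},
    {"symbol": "BAG1",   "role": "bag1"}
  ]
}
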