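{
  "signature_name": "mammaprint_related_genes",
  "genes": [
    {"symbol": "ALDH4A1"}, {"symbol": "BBC3"}, {"symbol": "C16orf61"},
    {"symbol": "LOC100288906"}, {"symbol": "LOC730018"}, {"symbol": "CCNE2"},
    {"symbol": "CDC42BPA"}, {"symbol": "CDCA7"}, {"symbol": "CENPA"},
    {"symbol": "COL4A2"}, {"symbol": "DCK"}, {"symbol": "DHX58"},
    {"symbol": "DIAPH3"}, {"symbol": "DTL"}, {"symbol": "EBF4"},
    {"symbol": "ECI2"}, {"symbol": "ECT2"}, {"symbol": "EGLN1"},
    {"symbol": "ESM1"}, {"symbol": "EXT1"}, {"symbol": "FGF18"},
    {"symbol": "FLT1"}, {"symbol": "GMPS"}, {"symbol": "GNAZ"},
    {"symbol": "GPR126"}, {"symbol": "GPR180"}, {"symbol": "GSTM3"},
    {"symbol": "HRASLS"}, {"symbol": "IGFBP5"}, {"symbol": "KDM7A"},
    {"symbol": "LIN9"}, {"symbol": "LPCAT1"}, {"symbol": "MCM6"},
    {"symbol": "MELK"}, {"symbol": "MMP9"}, {"symbol": "MTDH"},
    {"symbol": "NDC80"}, {"symbol": "NMU"}, {"symbol": "NUSAP1"},
    {"symbol": "ORC6L"}, {"symbol": "OXCT1"}, {"symbol": "PALM2AKAP2"},
    {"symbol": "PITRM1"}, {"symbol": "PRC1"}, {"symbol": "QSOX2"},
    {"symbol": "RAB6B"}, {"symbol": "RASSF7"}, {"symbol": "RECQL5"},
    {"symbol": "RFC4"}, {"symbol": "RTN4RL1"}, {"symbol": "RUNDC1"},
    {"symbol": "SCUBE2"}, {"symbol": "SERF1A"}, {"symbol": "SLC2A3"},
    {"symbol": "STK32B"}, {"symbol": "TGFB3"}, {"symbol": "TSPYL5"},
    {"symbol": "UCHL5"}, {"symbol": "WISP1"}, {"symbol": "ZNF385B"},
    {"symbol": "MSANTD3"}, {"symbol": "TMEM74B"},
    {"symbol": "AA555029_RC"}, {"symbol": "Contig20217_RC"},
    {"symbol": "Contig24252_RC"}, {"symbol": "Contig32125_RC"},
    {"symbol": "Contig35251_RC"}, {"symbol": "Contig38288_RC"},
    {"symbol": "Contig40831_RC"}, {"symbol": "Contig63649_RC"}
  ]
}
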