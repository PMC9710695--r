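{
  "cds_ids": ["c1", "c2", "c3", "c4"],
  "gene_ids": ["g", "h"],
  "multiblocks": [
    {"c2": [1, 5], "g": [4, 8]},
    {"c1": [1, 4], "c2": [6, 9], "c3": [1, 4], "g": [9, 12], "h": [7, 10]},
    {"c1": [5, 16], "c2": [10, 15], "c3": [5, 16], "c4": [1, 12], "g": [25, 36], "h": [23, 40]},
    {"c2": [16, 21], "g": [41, 46], "h": [43, 48]},
    {"c1": [17, 21], "c2": [22, 30], "c3": [17, 21], "c4": [13, 21], "g": [51, 59], "h": [51, 59]}
  ]
}
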