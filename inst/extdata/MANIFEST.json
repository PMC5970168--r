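{
  "cotton_exclusions.tsv": "4f18222ef156b89690da718c956027c5",
  "cotton_induced_genes.tsv": "b0b7394bcf5ffb1eb1043c4d45b9db82",
  "cotton_mapk_profiles.tsv": "b000a0971fbf0af4ee590e373ab5a2d1",
  "cotton_y2h_edges.tsv": "6290672f93739001c6835377a2205112"
}
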