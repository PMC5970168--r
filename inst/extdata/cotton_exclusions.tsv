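gene	reason
MKK10_1	low expression, not reliably detected in all tissues
MEKK19	low leaf expression, fold changes below 2 under all stresses
RAF17_2	low leaf expression, fold changes below 2 under all stresses
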