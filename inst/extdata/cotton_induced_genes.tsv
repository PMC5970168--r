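treatment	gene	peak_time_h	flag
JA	MEKK3_2	12	ok
JA	MEKK5_1	12	ok
JA	MEKK17	12	ok
JA	MEKK20	12	ok
JA	CTR1_1	12	ok
JA	RAF30_1	12	ok
JA	RAF32	12	ok
JA	ZIK1	24	ok
JA	MEKK10_1	8	ok
JA	RAF38_3	2	ok
H2O2	MEKK3_2	NA	ok
H2O2	MEKK17	NA	ok
H2O2	MEKK20	NA	ok
H2O2	CTR1_1	NA	ok
H2O2	RAF30_1	NA	ok
H2O2	RAF32	NA	ok
H2O2	ZIK1	NA	ok
ABA	MEKK5_1	0.5	ambiguous
ABA	MEKK10_1	0.5	ambiguous
ABA	RAF32	0.5	ambiguous
ABA	RAF38_3	0.5	ambiguous
ABA	ZIK1	8	ambiguous
ABA	MEKK4_2	8	ambiguous
ABA	MEKK17	8	ambiguous
ABA	MEKK20	1	ambiguous
ABA	RAF30_1	6	ambiguous
SA	ZIK1	6	reconstructed
SA	MEKK3_2	6	reconstructed
SA	MEKK4_2	6	reconstructed
SA	MEKK10_1	6	reconstructed
SA	MEKK17	6	reconstructed
SA	MEKK20	6	reconstructed
SA	RAF31_1	6	reconstructed
SA	RAF32	6	reconstructed
SA	RAF38_3	6	reconstructed
NaCl	ZIK1	10	ok
NaCl	MEKK17	10	ok
NaCl	RAF30_1	10	ok
NaCl	MEKK5_1	8	ok
NaCl	MEKK10_1	8	ok
NaCl	MEKK20	8	ok
NaCl	MEKK3_2	NA	ok
NaCl	MEKK4_2	NA	ok
NaCl	RAF31_1	NA	ok
NaCl	RAF32	NA	ok
NaCl	RAF38_3	NA	ok
PEG	MEKK17	1	ok
PEG	MEKK10_1	8	ok
PEG	MEKK20	8	ok
PEG	CTR1_1	8	ok
cold_4C	ZIK1	NA	ok
cold_4C	MEKK3_2	NA	ok
cold_4C	MEKK10_1	NA	ok
cold_4C	MEKK17	NA	ok
cold_4C	RAF32	NA	ok
heat_37C	MEKK3_2	2	ok
heat_37C	MEKK4_2	2	ok
heat_37C	RAF32	2	ok
heat_37C	RAF38_3	2	ok
heat_37C	MEKK17	12	ok
heat_37C	RAF31_1	12	ok
wounding	ZIK1	4	ok
wounding	MEKK3_2	4	ok
wounding	MEKK4_2	4	ok
wounding	MEKK5_1	4	ok
wounding	MEKK17	4	ok
wounding	MEKK20	4	ok
wounding	CTR1_1	4	ok
wounding	RAF31_1	4	ok
wounding	RAF32	4	ok
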