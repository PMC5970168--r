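gene	treatment	provenance
MPK3	JA	fixture
MPK3	H2O2	fixture
MPK3	ABA	fixture
MPK3	SA	fixture
MPK3	NaCl	fixture
MPK3	cold_4C	fixture
MPK3	heat_37C	fixture
MPK3	wounding	fixture
MPK6	JA	fixture
MPK6	H2O2	fixture
MPK6	ABA	fixture
MPK6	SA	fixture
MPK6	NaCl	fixture
MPK6	cold_4C	fixture
MPK6	heat_37C	fixture
MPK6	wounding	fixture
MPK12	JA	fixture
MPK12	H2O2	fixture
MPK12	ABA	fixture
MPK12	SA	fixture
MPK12	NaCl	fixture
MPK12	cold_4C	fixture
MPK12	heat_37C	fixture
MPK12	wounding	fixture
MPK13	JA	fixture
MPK13	H2O2	fixture
MPK13	ABA	fixture
MPK13	SA	fixture
MPK13	NaCl	fixture
MPK13	cold_4C	fixture
MPK13	heat_37C	fixture
MPK13	wounding	fixture
MPK18	JA	fixture
MPK18	H2O2	fixture
MPK18	SA	fixture
MPK18	NaCl	fixture
MPK18	cold_4C	fixture
MPK18	heat_37C	fixture
MPK18	wounding	fixture
MPK23	JA	fixture
MPK23	H2O2	fixture
MPK23	SA	fixture
MPK23	NaCl	fixture
MPK23	cold_4C	fixture
MPK23	heat_37C	fixture
MPK23	wounding	fixture
MPK7	JA	fixture
MPK7	H2O2	fixture
MPK7	ABA	fixture
MPK7	NaCl	fixture
MPK7	PEG	fixture
MPK7	heat_37C	fixture
MPK7	wounding	fixture
MPK15	JA	fixture
MPK15	H2O2	fixture
MPK15	ABA	fixture
MPK15	NaCl	fixture
MPK15	PEG	fixture
MPK15	heat_37C	fixture
MPK15	wounding	fixture
MPK25	JA	fixture
MPK25	H2O2	fixture
MPK25	ABA	fixture
MPK25	NaCl	fixture
MPK25	PEG	fixture
MPK25	heat_37C	fixture
MPK25	wounding	fixture
MPK20	JA	fixture
MPK20	H2O2	fixture
MPK20	ABA	fixture
MPK20	SA	fixture
MPK20	NaCl	fixture
MPK20	PEG	fixture
MPK20	heat_37C	fixture
MPK20	wounding	fixture
MPK8	JA	fixture
MPK8	H2O2	fixture
MPK8	ABA	fixture
MPK8	SA	fixture
MPK8	NaCl	fixture
MPK8	wounding	fixture
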