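lncrna_id	mrna_id	shared_mirnas	pcc	p_value
H19	ENO3	miR-103a-3p	0.23	2.9e-08
H19	SLC2A1	miR-148a-3p	0.21	4.8e-07
H19	HSP90AA1	miR-148a-3p;miR-152-3p	0.21	7.3e-07
H19	LOXL2	miR-29a-3p;miR-29c-3p	0.31	3.2e-14
MIR193BHG	LOXL2	miR-29a-3p;miR-29c-3p	0.30	2.1e-12
MIR193BHG	KPNA4	miR-29a-3p;miR-29c-3p	0.23	8.6e-08
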