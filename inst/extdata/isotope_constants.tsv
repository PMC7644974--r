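# Physical constants used by isodiel (all masses in Da).
# monoisotopic atomic masses
constant	value	unit
mass_C	12.0	Da
mass_H	1.00782503207	Da
mass_N	14.0030740048	Da
mass_O	15.9949146196	Da
mass_P	30.97376163	Da
mass_S	31.97207100	Da
# heavy-isotope mass differences
delta_13C_12C	1.0033548378	Da
delta_15N_14N	0.9970348934	Da
# other
electron_mass	0.00054857990907	Da
natural_13C_abundance	0.0107	fraction
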