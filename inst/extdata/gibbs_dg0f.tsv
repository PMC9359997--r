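species	dg0_prime	note
ethanol	58.10	standard transformed formation energy, pH 7, I = 0, 298.15 K (Alberty-style); illustrative constants, edit per study
acetate	-249.46	standard transformed formation energy, pH 7, I = 0, 298.15 K; illustrative
acetaldehyde	20.83	standard transformed formation energy, pH 7, I = 0, 298.15 K; illustrative
h2o	-155.66	water; activity fixed at 1 by convention
h2	79.91	dihydrogen gas; activity = partial pressure / 1 bar
h+	0.00	proton; absorbed into the transformed (pH 7) formalism, listed for stoichiometric bookkeeping
glucose	-426.71	standard transformed formation energy, pH 7, I = 0, 298.15 K; illustrative
co2	-547.10	total dissolved CO2; illustrative
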