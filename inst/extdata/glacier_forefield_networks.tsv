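# Published summary statistics of bacterial-fungal co-occurrence networks
# inferred for four Alpine calcareous glacier forefields (one network per
# location). linkage_density and edge_density are the printed (rounded)
# values; node and edge counts are exact.
location	n_nodes	n_bacteria	n_fungi	n_edges	linkage_density	edge_density	n_modules
Dachstein	1950	1527	423	10651	10.9	0.56	29
Griessen	2099	1613	486	14406	13.7	0.65	27
Marmolada	2196	1645	551	16411	14.9	0.68	24
Tsanfleuron	2257	1920	337	12825	11.4	0.5	25
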