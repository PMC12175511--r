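# Published core-microbiome counts for the same four-glacier study design:
# OTUs passing the per-domain occupancy threshold in every location (core)
# and total OTUs per domain.
domain	core_otus	total_otus
bacteria	474	13452
fungi	84	4312
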