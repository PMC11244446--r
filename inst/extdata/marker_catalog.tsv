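domain_accession	domain_name	class	weight
PF04947	Pox_VLTF3	GEVE	required-any
PF04665	Pox_A32_ATPase	GEVE	required-any
PF03288	Pox_D5_primase	GEVE	required-any
PF04451	Capsid_NCLDV_major	GEVE	required-any
PF00136	DNA_pol_B	adintovirus	required-any
PF17475	Adinto_capsid_minor	adintovirus	required-any
PF16904	Adinto_capsid_major	adintovirus	required-any
PF05869	Dam_methylase	adintovirus	supporting
PF00589	Tyrosine_recombinase	plavaka	required-any
PF20469	Plavaka_transposase	plavaka	required-any
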