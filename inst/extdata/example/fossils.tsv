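taxon_name	rank	parent_name	validity	senior_name	material_class	is_extinct
Multituberculata	order	Mammalia	DISUSED		BODY_DIAGNOSTIC	true
Ptilodus	genus	Multituberculata	VALID		BODY_DIAGNOSTIC	true
Brontotheriidae	family	Mammalia	VALID		BODY_DIAGNOSTIC	true
Brontotherium	genus	Brontotheriidae	VALID		BODY_DIAGNOSTIC	true
Titanops	genus	Brontotheriidae	SYNONYM_OF	Brontotherium	BODY_DIAGNOSTIC	true
Megalosauropus	genus	Mammalia	VALID		TRACE	true
Doubtfulia	genus		VALID		BODY_DIAGNOSTIC	true
Invalidodon	genus	Brontotheriidae	INVALID		BODY_DIAGNOSTIC	true
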