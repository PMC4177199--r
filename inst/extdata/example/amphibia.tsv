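order	family	genus	species	common_name	synonyms
Anura	Ranidae	Rana	catesbeiana	American Bullfrog	Lithobates catesbeianus
Anura	Ranidae	Rana	temporaria	European Common Frog	
Caudata	Ambystomatidae	Ambystoma	mexicanum	Axolotl	
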