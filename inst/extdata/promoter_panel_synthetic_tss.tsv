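id	tss_index	element
chicken	150	tata_like
duck	150	tata_like
zebra_finch	150	tata_like
falcon	150	tata_like
ostrich	150	tata_like
tinamou	150	tata_like
pigeon	150	tata_like
egret	150	tata_like
mesite	150	tata_like
canary	150	tata_like
emperor_penguin	150	tata_like
adelie_penguin	150	tata_like
loon	150	canonical_tata
lizard	150	canonical_tata
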