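gene	change	label	source
PIK3CA	H1047R	GOF	cosmic_like
PIK3CA	H1047L	GOF	cosmic_like
PIK3CA	D350G	GOF	literature
TP53	L111*	LOF	cosmic_like
TP53	Y126N	LOF	cosmic_like
TP53	H179Y	GOF	literature
TP53	S241F	GOF+DN	literature
TP53	R248W	GOF	literature
TP53	V274L	dominant_negative	literature
PTEN	I101T	predicted_pathogenic	clinvar_like
PLCG1	S345F	GOF	literature
DSCAM	R1798*	predicted_pathogenic	literature
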