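id	name	formula	keto_acid
M001	pyruvate	C3H4O3	TRUE
M002	oxaloacetate	C4H4O5	TRUE
M003	2-oxoglutarate	C5H6O5	TRUE
M004	glyoxylate	C2H2O3	TRUE
M005	2-oxobutanoate	C4H6O3	TRUE
M006	3-methyl-2-oxobutanoate	C5H8O3	TRUE
M007	4-methyl-2-oxopentanoate	C6H10O3	TRUE
M008	3-methyl-2-oxopentanoate	C6H10O3	TRUE
M009	phenylpyruvate	C9H8O3	TRUE
M010	4-hydroxyphenylpyruvate	C9H8O4	TRUE
M011	glucose	C6H12O6	FALSE
M012	lactate	C3H6O3	FALSE
M013	citrate	C6H8O7	FALSE
M014	isocitrate	C6H8O7	FALSE
M015	cis-aconitate	C6H6O6	FALSE
M016	glutamate	C5H9NO4	FALSE
M017	glutamine	C5H10N2O3	FALSE
M018	glutathione	C10H17N3O6S	FALSE
M019	ATP	C10H16N5O13P3	FALSE
M020	AMP	C10H14N5O7P	FALSE
M021	glycerol 3-phosphate	C3H9O6P	FALSE
M022	acetylcarnitine	C9H17NO4	FALSE
M023	xanthine	C5H4N4O2	FALSE
M024	dihydroorotate	C5H6N2O4	FALSE
M025	ribose 5-phosphate	C5H11O8P	FALSE
M026	hexadecanal	C16H32O	FALSE
M027	alanine	C3H7NO2	FALSE
M028	serine	C3H7NO3	FALSE
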