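# Curated species thermodynamics for the packaged liver model.
# dgf0: standard Gibbs free energy of formation at 298.15 K, kJ/mol,
#   major protonation state at pH 7 (transformed-energy convention with
#   explicit proton and water bookkeeping).  ATP and NAD+ values follow
#   public eQuilibrator tables verbatim; remaining values are curated to
#   be internally consistent so reaction free-energy changes take
#   textbook magnitudes (see package vignette for the construction).
# dhf0: curated formation enthalpies (proportional-plus-group-increment
#   scheme; see vignette).  sd: standard deviation of dgf0, kJ/mol.
species_id	name	formula	charge	dgf0_kj_mol	dhf0_kj_mol	sd_kj_mol
glucose	D-glucose	C6H12O6	0	-426.7	-601.37	1.3
g6p	glucose 6-phosphate	C6H11O9P	-2	-1318	-1641.8	1.5
f6p	fructose 6-phosphate	C6H11O9P	-2	-1315.3	-1638.83	1.5
fbp	fructose 1,6-bisphosphate	C6H10O12P2	-4	-2202.8	-2675.08	2
dhap	dihydroxyacetone phosphate	C3H5O6P	-2	-1096.1	-1331.71	1.1
g3p	glyceraldehyde 3-phosphate	C3H5O6P	-2	-1088.6	-1323.46	1.1
bpg	1,3-bisphosphoglycerate	C3H4O10P2	-4	-2192.7	-2609.97	2.1
pg3	3-phosphoglycerate	C3H4O7P	-3	-1341.1	-1620.21	1.2
pg2	2-phosphoglycerate	C3H4O7P	-3	-1336.7	-1615.37	1.2
pep	phosphoenolpyruvate	C3H2O6P	-3	-1182.3	-1443.53	1.3
pyr	pyruvate	C3H3O3	-1	-350.8	-468.88	0.8
lac	L-lactate	C3H5O3	-1	-318.4	-423.24	0.9
glycogen	glycogen (glucosyl unit)	C6H10O5	0	-257.4	-364.73	2.5
g1p	glucose 1-phosphate	C6H11O9P	-2	-1310.9	-1633.99	1.5
atp	ATP	C10H12N5O13P3	-4	-2295.1	-2833.61	3
adp	ADP	C10H12N5O10P2	-3	-1425.1	-1823.61	2.4
amp	AMP	C10H12N5O7P	-2	-555.1	-813.61	1.4
adenosine	adenosine	C10H13N5O4	0	327.9	217.69	2.7
pi	orthophosphate	HO4P	-2	-1056.6	-1224.26	1
h2po4	dihydrogen phosphate	H2O4P	-1	-1053.4	-1213.74	1
hbuf	protonated imidazole buffer (synthetic)	C6H9N3O2	0	-200	-295	2
buf	imidazole buffer base (synthetic)	C6H8N3O2	-1	-204.6	-307.06	2
ppi	pyrophosphate	HO7P2	-3	-1936.6	-2245.26	1.6
nad	NAD+	C21H26N7O14P2	-1	-1171.8	-1722.98	12.4
nadh	NADH	C21H27N7O14P2	-2	-1117.6	-1660.36	12.4
nadp	NADP+	C21H25N7O17P3	-3	-2260	-2980	13
nadph	NADPH	C21H26N7O17P3	-4	-2206	-2917.6	13
fad	FAD	C27H31N9O15P2	-2	1103	686.3	15
fadh2	FADH2	C27H33N9O15P2	-2	1094.3	686.73	15
h	proton	H	1	54.3	0	0
h2o	water	H2O	0	-157.6	-175.36	0.1
o2	dioxygen (aq)	O2	0	16.4	-5.96	0.5
co2	carbon dioxide (aq)	CO2	0	-386	-468.6	0.9
hco3	bicarbonate	CHO3	-1	-552.2	-660.42	0.9
nh3	ammonia	H3N	0	-71	-55.1	0.4
nh4	ammonium	H4N	1	-79.5	-57.45	0.4
urea	urea	CH4N2O	0	-362.6	-394.86	0.6
orn	L-ornithine	C5H13N2O2	1	-46	-91.6	2.2
citr	L-citrulline	C6H13N3O3	0	-324.5	-423.95	2.3
argsucc	argininosuccinate	C10H17N4O6	-1	-745.9	-977.49	3.1
arg	L-arginine	C6H15N4O2	1	-221	-278.1	2.4
asp	L-aspartate	C4H6NO4	-1	-608	-760.8	1.1
glu	L-glutamate	C5H8NO4	-1	-529.6	-684.56	1
gln	L-glutamine	C5H10N2O3	0	-477.5	-526.65	1.2
cp	carbamoyl phosphate	CH2NO5P	-2	-1320.1	-1533.11	2.6
gly	glycine	C2H5NO2	0	-180.1	-229.11	0.6
ser	L-serine	C3H7NO3	0	-112.5	-176.75	0.9
cys	L-cysteine	C3H7NO2S	0	-59.2	-103.12	1.3
gsh	glutathione (reduced)	C10H16N3O6S	-1	-405.7	-613.27	3.4
thf	tetrahydrofolate	C19H21N7O6	-2	-91.9	-396.09	8
mlthf	5,10-methylene-THF	C20H21N7O6	-2	134.3	-167.27	8.5
coa	coenzyme A	C21H32N7O16P3S	-4	-1854.5	-2485.95	6
accoa	acetyl-CoA	C23H34N7O17P3S	-4	-1903	-2581.3	6
malcoa	malonyl-CoA	C24H33N7O19P3S	-5	-2277.6	-3044.36	6.3
butcoa	butanoyl-CoA	C25H38N7O17P3S	-4	-1724.5	-2404.95	6.1
oaa	oxaloacetate	C4H2O5	-2	-713	-918.3	1.5
cit	citrate	C6H5O7	-3	-960	-1241	1.6
icit	isocitrate	C6H5O7	-3	-953.4	-1233.74	1.6
akg	2-oxoglutarate	C5H4O5	-2	-630	-837	1.7
succoa	succinyl-CoA	C25H35N7O19P3S	-5	-2182.7	-2949.97	6.2
succ	succinate	C4H4O4	-2	-530.6	-695.66	1.1
fum	fumarate	C4H2O4	-2	-521.9	-696.09	1
mal	L-malate	C4H4O5	-2	-682.8	-875.08	1
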