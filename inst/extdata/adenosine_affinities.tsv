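# Experimental binding free energies (kcal/mol) of adenosine A1/A2A
# receptor ligands, derived from published radioligand-binding dissociation
# constants; NA marks a ligand not measured at that receptor.
ligand	abbreviation	type	pdb	dg_a2a	err_a2a	dg_a1	err_a1
CGS15943	CGS	antagonist	NA	-12.70	0.06	-12.49	0.10
LUF5834	LUF34	agonist	NA	-9.77	0.25	-11.53	0.10
LUF5963	LUF3	antagonist	NA	-8.70	0.15	-10.96	0.05
LUF5964	LUF4	antagonist	NA	-9.28	0.42	-12.59	0.09
LUF5967	LUF7	antagonist	NA	-8.54	0.33	-12.03	0.10
NECA	NECA	agonist	2YDV	-9.52	0.13	-8.69	0.13
theophylline	Theo	antagonist	5MZJ	-7.16	0.09	-7.68	0.11
XAC	XAC	antagonist	3REY	-10.11	0.15	-10.86	0.06
CGS21680	NGI	agonist	4UHR	-8.14	0.09	NA	NA
LUF5448	LUF8	agonist	NA	-8.49	0.15	NA	NA
LUF5549	LUF9	agonist	NA	-9.90	0.14	NA	NA
LUF5550	LUF0	agonist	NA	-8.84	0.15	NA	NA
LUF5631	LUF1	agonist	NA	-9.17	0.20	NA	NA
LUF5833	LUF33	agonist	NA	-9.83	0.27	NA	NA
LUF5835	LUF35	agonist	NA	-9.85	0.26	NA	NA
UK-432097	UK	agonist	3QAK	-10.31	0.07	NA	NA
ZM-241385	ZMA	inverse agonist	5IU4	-11.71	0.09	NA	NA
LUF6057	7	agonist	NA	NA	NA	-11.19	0.15
CCPA	CCPA	agonist	NA	NA	NA	-9.59	0.10
CHEMBL3613119	119	agonist	NA	NA	NA	-11.64	0.10
CHEMBL3613120	120	agonist	NA	NA	NA	-11.17	0.22
DPCPX	DPX	inverse agonist	NA	NA	NA	-12.11	0.07
FSCPX	FPX	antagonist	NA	NA	NA	-11.91	0.14
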