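# Experimentally determined relative binding free energies (kcal/mol) for
# the ligand-pair transformations amenable to alchemical calculation:
# ddg = dG(L2) - dG(L1), uncertainties propagated in quadrature, printed to
# two decimals. NA marks a receptor at which one ligand lacks a measurement.
l1	l2	ddg_A2A	err_A2A	ddg_A1	err_A1
LUF3	LUF4	-0.58	0.45	-1.63	0.10
LUF3	LUF7	0.16	0.36	-1.07	0.11
LUF4	LUF7	0.74	0.53	0.56	0.13
Theo	XAC	-2.95	0.17	-3.18	0.13
LUF8	LUF1	-0.68	0.25	NA	NA
LUF34	LUF35	-0.08	0.36	NA	NA
LUF33	LUF34	0.06	0.37	NA	NA
LUF33	LUF35	-0.02	0.37	NA	NA
NECA	CCPA	NA	NA	-0.90	0.16
119	120	NA	NA	0.47	0.24
XAC	DPX	NA	NA	-1.25	0.09
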