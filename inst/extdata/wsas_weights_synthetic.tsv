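# Synthetic WSAS weight file illustrating the parameter-file format
# (atom_type, weight per A^2). These are NOT literature calibration values;
# production weights must be supplied by the user.
# k = 0.3
# r_prob = 1.4
C	1.0
N	0.5
O	0.5
H	0.25
S	1.0
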