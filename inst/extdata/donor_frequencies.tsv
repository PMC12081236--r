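position	A	C	G	T
E-3	0.330	0.370	0.180	0.120
E-2	0.600	0.130	0.130	0.140
E-1	0.080	0.030	0.800	0.090
+1	0.003	0.004	0.990	0.003
+2	0.003	0.012	0.003	0.982
+3	0.495	0.030	0.450	0.025
+4	0.705	0.075	0.115	0.105
+5	0.060	0.055	0.845	0.040
+6	0.150	0.160	0.210	0.480
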