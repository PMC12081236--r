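position	A	C	G	T
-20	0.100	0.300	0.110	0.490
-19	0.095	0.310	0.105	0.490
-18	0.090	0.310	0.100	0.500
-17	0.090	0.320	0.095	0.495
-16	0.090	0.320	0.090	0.500
-15	0.085	0.325	0.090	0.500
-14	0.085	0.330	0.085	0.500
-13	0.080	0.330	0.085	0.505
-12	0.080	0.335	0.080	0.505
-11	0.080	0.340	0.080	0.500
-10	0.075	0.345	0.075	0.505
-9	0.075	0.350	0.075	0.500
-8	0.075	0.350	0.070	0.505
-7	0.070	0.355	0.070	0.505
-6	0.070	0.350	0.080	0.500
-5	0.080	0.370	0.070	0.480
-4	0.240	0.300	0.210	0.250
-3	0.030	0.640	0.005	0.325
-2	0.991	0.003	0.003	0.003
-1	0.003	0.003	0.991	0.003
E+1	0.250	0.140	0.500	0.110
E+2	0.290	0.200	0.240	0.270
E+3	0.240	0.260	0.260	0.240
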