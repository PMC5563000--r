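locus_tag	contrast	qpcr_fold	rnaseq_fold
CCI6_RS21730	salt	2.100	2.360
CCI6_RS17915	salt	3.120	3.240
CCI6_RS19875	salt	2.500	4.910
CCI6_RS17580	salt	3.140	3.480
CCI6_RS16000	salt	1.890	2.183
CCI6_RS18570	salt	1.320	1.230
CCI6_RS06495	salt	1.400	1.500
CCI6_RS02325	salt	3.500	3.840
CCI6_RS12340	salt	-1.300	-4.000
CCI6_RS08505	salt	3.230	3.590
CCI6_RS19950	salt	10.021	12.061
CCI6_RS21730	osmotic	1.100	-6.000
CCI6_RS17915	osmotic	1.820	1.980
CCI6_RS19875	osmotic	3.011	11.210
CCI6_RS17580	osmotic	2.120	1.520
CCI6_RS16000	osmotic	-0.500	-1.200
CCI6_RS18570	osmotic	1.511	1.380
CCI6_RS06495	osmotic	-1.310	-2.020
CCI6_RS02325	osmotic	2.800	3.860
CCI6_RS12340	osmotic	1.300	-9.000
CCI6_RS08505	osmotic	1.150	1.051
CCI6_RS19950	osmotic	18.231	21.585
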