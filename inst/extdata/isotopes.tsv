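element	isotope	mass	abundance
C	12	12.0	0.9893
C	13	13.0033548378	0.0107
H	1	1.00782503207	0.999885
H	2	2.0141017778	0.000115
N	14	14.0030740048	0.99636
N	15	15.0001088982	0.00364
O	16	15.99491461956	0.99757
O	17	16.9991317	0.00038
O	18	17.999161	0.00205
S	32	31.972071	0.9499
S	33	32.97145876	0.0075
S	34	33.9678669	0.0425
S	36	35.96708076	0.0001
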