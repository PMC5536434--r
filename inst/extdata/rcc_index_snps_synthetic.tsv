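locus	chrom	pos	id
2p21	chr2	1500001	rs7579899
12q24.31	chr12	9500001	rs4765623
11q13.3	chr11	6900001	rs7105934
12p12.1	chr12	2600001	rs718314
6q22.31	chr6	11800001	rs25422
8q24.21	chr8	12800001	rs6470588
2q22.3	chr2	14400001	rs12105918
5p13.3	chr5	3300001	rs10054504
1q24.1	chr1	16900001	rs3845536
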