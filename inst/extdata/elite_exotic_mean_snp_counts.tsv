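unit	elite_mean	exotic_mean
chr1A	45734	47865
chr1B	49306	55034
chr1D	9372	9423
chr2A	46243	53899
chr2B	60874	62237
chr2D	9284	12458
chr3A	33536	35550
chr3B	97429	97734
chr3D	7892	23853
chr4A	35341	34540
chr4B	12840	30796
chr4D	3597	4099
chr5A	36687	38698
chr5B	56866	57567
chr5D	5850	8960
chr6A	40510	41888
chr6B	63171	65299
chr6D	5684	8218
chr7A	53058	54033
chr7B	44757	55862
chr7D	7872	13268
A	291110	306473
B	385242	424530
D	49550	80280
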