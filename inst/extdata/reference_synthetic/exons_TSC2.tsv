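# TSC2 exon table, CDS coordinates (1-based inclusive), coding-exon numbering 1-41
# (the single non-coding guiding exon is recorded in transcripts.tsv, not here).
# SYNTHETIC boundaries: constructed to be consistent with the published domain
# placements (LZD aa81-98 in exon 3, CCD1 aa346-371 in exon 10, CCD2 aa1008-1021 in
# exon 26, TAD1 aa1163-1259 in exons 29-30, GAPD aa1517-1674 in exons 34-38,
# TAD2 aa1690-1744 in exons 39-40, CaBD aa1740-1755 in exons 40-41); they are
# replaceable configuration, not LOVD/RefSeq database coordinates.
exon	cds_start	cds_end	coding
1	1	120	TRUE
2	121	240	TRUE
3	241	360	TRUE
4	361	480	TRUE
5	481	600	TRUE
6	601	720	TRUE
7	721	840	TRUE
8	841	960	TRUE
9	961	1035	TRUE
10	1036	1150	TRUE
11	1151	1280	TRUE
12	1281	1410	TRUE
13	1411	1540	TRUE
14	1541	1670	TRUE
15	1671	1800	TRUE
16	1801	1930	TRUE
17	1931	2060	TRUE
18	2061	2190	TRUE
19	2191	2320	TRUE
20	2321	2450	TRUE
21	2451	2580	TRUE
22	2581	2710	TRUE
23	2711	2840	TRUE
24	2841	2960	TRUE
25	2961	3021	TRUE
26	3022	3130	TRUE
27	3131	3280	TRUE
28	3281	3432	TRUE
29	3433	3611	TRUE
30	3612	3790	TRUE
31	3791	3960	TRUE
32	3961	4200	TRUE
33	4201	4548	TRUE
34	4549	4660	TRUE
35	4661	4760	TRUE
36	4761	4860	TRUE
37	4861	4960	TRUE
38	4961	5060	TRUE
39	5061	5160	TRUE
40	5161	5240	TRUE
41	5241	5424	TRUE
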