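# TSC1 exon table, CDS coordinates (1-based inclusive), NM_000368.4 numbering.
# Exons 1-2 are non-coding (empty CDS span). SYNTHETIC boundaries: constructed to be
# consistent with the published domain placements (TMD aa127-144 in exon 6, the c.737
# substitution at the 3' end of exon 8, CCD aa730-996 within exons 18-22); they are
# replaceable configuration, not LOVD/RefSeq database coordinates.
exon	cds_start	cds_end	coding
1	NA	NA	FALSE
2	NA	NA	FALSE
3	1	150	TRUE
4	151	280	TRUE
5	281	378	TRUE
6	379	500	TRUE
7	501	640	TRUE
8	641	737	TRUE
9	738	900	TRUE
10	901	1060	TRUE
11	1061	1220	TRUE
12	1221	1380	TRUE
13	1381	1540	TRUE
14	1541	1700	TRUE
15	1701	1860	TRUE
16	1861	2020	TRUE
17	2021	2180	TRUE
18	2181	2350	TRUE
19	2351	2520	TRUE
20	2521	2690	TRUE
21	2691	2860	TRUE
22	2861	3030	TRUE
23	3031	3495	TRUE
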