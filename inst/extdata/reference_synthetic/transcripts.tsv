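# Transcript geometry for the TSC1 (NM_000368.4) and TSC2 (NM_000548.3) coding sequences.
# SYNTHETIC coordinates: CDS and protein lengths are the canonical hamartin (1164 aa)
# and tuberin (1807 aa) values; exon boundary positions in exons_<gene>.tsv are
# constructed, not database coordinates (see package vignette). noncoding_exons is the
# number of leading exons with no coding content (TSC1: exons 1-2; TSC2: 1 guiding exon).
gene	transcript_id	cds_length	protein_length	noncoding_exons
TSC1	NM_000368.4	3495	1164	2
TSC2	NM_000548.3	5424	1807	1
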