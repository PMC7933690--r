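# TSC1 N-/C-terminal split by exon 15 (exon 15 itself on the N-terminal side;
# configurable at load time). Exon numbers are NM_000368.4 exon numbers; the
# non-coding exons 1-2 carry no variants but are covered for completeness.
name	exon_start	exon_end
N-terminal	1	15
C-terminal	16	23
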