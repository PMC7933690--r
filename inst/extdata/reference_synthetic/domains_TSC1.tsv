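# Hamartin (TSC1) functional domains. Amino-acid intervals are 1-based inclusive
# residue indices; TID is defined only by its exon range in the literature, so its
# aa columns are left empty rather than guessed.
# TMD: transmembrane domain; TID: tuberin interaction domain; CCD: coiled coil domain.
name	aa_start	aa_end	exon_start	exon_end
TMD	127	144	6	6
TID	NA	NA	8	11
CCD	730	996	18	22
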