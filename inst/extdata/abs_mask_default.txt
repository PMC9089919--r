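# Default antigen-binding-site mask: 18 codon positions (1-based, over the
# 80 complete codons of the exon 2 amplicon) corresponding to the
# peptide-contact residues of the human MHC class II DR beta1 domain, the
# standard proxy used when the study species lacks a solved structure.
9
11
13
28
30
32
37
38
47
56
60
61
65
68
70
71
74
78
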