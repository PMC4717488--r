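anticodon	amino_acid	gene_copies	inosine34	t6a37
AGC	Ala	11	TRUE	FALSE
UGC	Ala	5	FALSE	FALSE
ACG	Arg	6	TRUE	FALSE
CCG	Arg	1	FALSE	FALSE
UCU	Arg	11	FALSE	TRUE
CCU	Arg	1	FALSE	TRUE
GUU	Asn	10	FALSE	TRUE
GUC	Asp	16	FALSE	FALSE
GCA	Cys	4	FALSE	FALSE
UUG	Gln	9	FALSE	FALSE
CUG	Gln	1	FALSE	FALSE
UUC	Glu	14	FALSE	FALSE
CUC	Glu	2	FALSE	FALSE
GCC	Gly	16	FALSE	FALSE
UCC	Gly	3	FALSE	FALSE
CCC	Gly	2	FALSE	FALSE
GUG	His	7	FALSE	FALSE
AAU	Ile	13	TRUE	TRUE
UAU	Ile	2	FALSE	TRUE
CAA	Leu	10	FALSE	FALSE
UAA	Leu	7	FALSE	FALSE
UAG	Leu	3	FALSE	FALSE
GAG	Leu	1	FALSE	FALSE
CUU	Lys	14	FALSE	TRUE
UUU	Lys	7	FALSE	TRUE
CAU	Met	5	FALSE	TRUE
CAU	iMet	4	FALSE	TRUE
GAA	Phe	10	FALSE	FALSE
AGG	Pro	10	TRUE	FALSE
UGG	Pro	2	FALSE	FALSE
AGA	Ser	11	TRUE	FALSE
UGA	Ser	3	FALSE	FALSE
CGA	Ser	1	FALSE	FALSE
GCU	Ser	4	FALSE	TRUE
AGU	Thr	11	TRUE	TRUE
UGU	Thr	4	FALSE	TRUE
CGU	Thr	1	FALSE	TRUE
CCA	Trp	6	FALSE	FALSE
GUA	Tyr	8	FALSE	FALSE
AAC	Val	14	TRUE	FALSE
UAC	Val	2	FALSE	FALSE
CAC	Val	2	FALSE	FALSE
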