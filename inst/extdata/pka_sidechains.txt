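# Canonical pKa values for titratable groups (EMBOSS set)
# sign: +1 basic group (protonated below pKa), -1 acidic group
group pKa sign
NTERM 8.6 1
CTERM 3.6 -1
K 10.8 1
R 12.5 1
H 6.5 1
D 3.9 -1
E 4.1 -1
C 8.5 -1
Y 10.1 -1
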