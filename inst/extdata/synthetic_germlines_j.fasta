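>SYNJ1*01 anchor=8
AGCATTATGGGATTGGATGTCGGGGGCCGACGCAATTAGC
>SYNJ2*01 anchor=11
GGACGCTTAGTGGGTTAATAAAAGTCAACTAGGGCCGAACTCG
>SYNJ3*01 anchor=8
TTAAGTCTGGTGCAATACTTCCCATAACTTTGTGCCACAG
>SYNJ4*01 anchor=8
TCGGGGATGGGTACTGCGAAACTATTTTGCTGCGGAGATC
>SYNJ5*01 anchor=7
CGACTATGGCCCCTAAAACCGTCCGTTTCCGGCGCTAGG
>SYNJ6*01 anchor=12
AACCGAAACCATGGGGCTCCGTGCTACTGGAAACAGCCTTCTAT
>SYNJ7*01 anchor=9
CGGGGCTCTGGACCGTTCTCGTCTGTTTATGTTCCTGGATG
>SYNJ8*01 anchor=13
GGCTACTTTACATGGGTCAACAGCGGGTTACCAACTGCCATATAT
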