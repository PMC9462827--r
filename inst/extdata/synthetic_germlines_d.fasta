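>SYND1*01
CCAGTCAAATTTTACTG
>SYND2*01
GTACAATCAATCGACC
>SYND3*01
TAACCGAAAACTGTAGT
>SYND4*01
AGGTTAGATTCCCGGAGACGG
>SYND5*01
GGGTCAGTGAATGGTCC
>SYND6*01
CCGTGAGGGAAATCG
>SYND7*01
TACCACGCCCAAT
>SYND8*01
GGCTAGAGTTAGGCTAC
>SYND9*01
TGGATGTTAATTTTCGAGCTTT
>SYND10*01
TGCCATCGATAGAGACTAGTT
>SYND11*01
CATCCTGATAAACCCGCTCA
>SYND12*01
GGACCGCGACGGAT
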