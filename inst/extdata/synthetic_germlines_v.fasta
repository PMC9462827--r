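>SYNV1-1*01
TCAAGGAGTGACTACAGGTCACTGCTGAGGGTACCCGCATGGATTCATTGCGCATCGCGTAGCCCCAGACATCCGTTACACGAGTGTATATTCAAACACGTTAAGCACATACTCCAGAGAGTGCGGACTTCTACGCTTAGTTATCGTCTCTACAGTCTGATGGTAACCAATAAACGTGTTCTAATAGAGTTCCGTCCGTTACACTATACATGCAGCGAGCCCCGTAGATTAATAAGGTATGCTAGACCATCTTTCTGT
>SYNV1-2*01
GCAGACGTTTACGATCCCGCTAATTGCTCAACACTATCCTGGGTGGGTCGGCGTTACCGCACTAATTGTGGACGGGATAAGCTCGCTTGGGTTTCTCCCTTCAACACCATCCAAAGACCTCGTGAAAGCATAAACTCACCCGGATTACTATCTGCGACTTTCGCTCTTAAAACTGCGACGGAGTTTAAGCAAAAATTTGACCGATACGTTGAAGCAAAGAGTACTAGTCGATATCCCTTATTCTCACTACATTGGCGGGAGCTCACCATGAAGTGT
>SYNV1-3*01
GTGACCCCTAGTAGAAATGACAGGCATATATCAGGGCCCGCCAATACGGCCGTTATTTTCGAGCCCCTGTCCAGCCTCAAGTCCGCGAAGCCACCTAACAGGGACTCACCGAACGTACATGCCGGTACGCGAATCAGCGCACAATTGGTTTTGTTGGCGCTATCCGCCGGATCGCCCCCCAATATTAAGGCTTCGCATAAATCTAATTCCACTACTGAACACCGGCCCACCTGTCTTCGGAGAACACAACACTACGAGGTGCGCCCCCCATGT
>SYNV1-4*01
TTTGGTTGTAGAGTCAGCGCACGTGCTTATTCTTATCCAGCCATCAAACGTGCGCGGTGGTATCTCGAAGATCAATCCCCAAACGTATTACCCAGGTTGTTTCACACAGCGCTCAGACGCGTCTCAAGTCTGTACAGCCAGGATCCCCCGCCTGTCCGACGGAGAGGCGAAATCGAAGGGCAGGGATGTGTGCATTATCAGCACCGTGAGATCCTCCGTAGACGCTCTCGATATGGAGCCCAATTACCTTGCATAGTCGCCTGCTTAGCCAGTCTCTGT
>SYNV2-1*01
CGACACGCTACCCGCATGAAAAACTCCCCAGCTTCCAACTCAGATTTTGGAGACATTTCCAATAAGGAAGACTTGCTAACCAGTAATGGCTACTGTTGGATTGCAGTACTCAACACGGTGAAGGAAATCTGTATTATATGCGGGTCCCCCAGGGTTAGTCCAATACGACCCCGACTTTTAGTTCAACTTAGAAGAATTTTATATCAAAGCAGATTTGGTTATGCGAGTCAACAAATACGGGTGTCGTGGAATCGACGTACGGCGCTTCTGATTTGT
>SYNV2-2*01
CCCCGTATTAGGGTTCTTACGAGTTCCTCGCCTCCGTTACCGGTTCTGATTTACCCACACCGATGTCCGTGTGTGTATAGAGGGGTCAATGAGTTCAAACCGTGGTTTCAAATTAAGTCGTCTTTACTATGTGGCTCCCTGTTAGTTTCGGTTTTCCACTGTCTGAGGGATCCGGGAAAGCGAATTTCTTTGCACCGACATCTAGAACTGCAGGTCGAAGACAGCTGCCTCGGACTCGGCCTGATCCTCGTTCTTTGT
>SYNV2-3*01
GGTAGGGACGTATCCGGGCTTTTCCACAGTGCATATACAGTCACATTCTCGTCCAAGACGAAGCAAAATGCGAGATGTGGACGCTACTTTTACTGGATCACAACATGGAGCATGGATTCTCAACTATCTAGGGTCCGATCCAAGGGGCGCTATTGTGGTGAGGACGCTTCCGTCCCCCGCGGTCGGCTCAGTACCTTAACAAGCTGCTCTGTCGCACAACTGGCACCCGTTGACAAGATACGAGAAGTGGAGATGCTATGGGGAAACTGTAAGCCGCATTGT
>SYNV2-4*01
ATCTCCTATCGGGATAATGTGCGCGGTGAGGGCGCGGGGGGCTCGTCCGAGCTGAGGTCCCATCTCGGCTCCTACAGATTCTGGTCGTGCTTACTGCAACAATCGGTGTCATTTTGTGTAGGAAACGCCCTTAACCCAAGTTGCACGTTCCGTATAACACCCGAGGCAGATTCACTTCTTTTGGTCAACGTCCCACCCCTGTCCATTACGCTTAGATTTGCCGGATGCGCTGGGCTGTGTCTGAGAAGAACCGTTTTTTGTTTCCATGGGCAAAAGTCTTGT
>SYNV3-1*01
AGTGGCTGGCTTTTTTCGTCTGCGAGAGCAGATACGGCAGGTAGTTCTGGCTGGCTACCAGTGGACGCGAGTGTTTTTTACCTTTTCAACGGCATGCGGGAGGCGGTATTCGTCCCTTCCCTCGAGGACTTACACCATACTCTCGTTTTAATGACTATACGAGTTGCGGGTTCATCCATTGCTATCATAGAGGCCAGTCTACGATACGGAACTGTGATGTTTTGGGGGCGTGCGGCAGTCGTAGCAGTTCTCCTGTGGACATTTCTGTGCGCCAGGTGT
>SYNV3-2*01
CGCCCCGTGGTGGGTAAGCCACTTATCTGTGTGCATTACCTCCAGTTCTCGAATGTGCATCCCCACCCCTTAAGTGTACTGAGATCGGTGACACCCTTCGATCGTGTATCCATTTGGGTAGGGCCAAGGGTCGGGCAAACGATGCGCTACTTCCCCTTTGCACATTATCCGGAGAGTGTGGTGGCCCGTCTGATGGCCGAGAGGACGCATAGCGTTGACGTAGCGTCAACGTTAGCCATTTTCCTTCATCGCTCTGGTCATGTACTGAAATGCTGT
>SYNV3-3*01
TTATCCATCCCTCCGGAGAATTTTGACGAAAACATTAGAACAGTACGCGAATGCTATAGCGCTAGGCTGAGTACAGTTATCGAGCCTTGCAAATCCTGTGTAGTGCACAACGTCTTATGCACTGGACGTGGTGGTCGGCTCCTAGCCTCTAAGATTAGGTTTATGCGCGGTTCACTGATGTCTCCTTTAGAGGGCCAACGTGCCAGACGTTACGGCTGCGAAAGGAAGAGCGTGACTCCAATGCTCTCTCACCCGGAAGAACGAAGGCGAGACGTCAATCGGGGCAGTTGT
>SYNV3-4*01
ACGCCATTAAGGCCACAAGGAGCGGATACGACAGTGCCAAGACATTGTTGTCCTCCATCGACCAAGTTTGGCATGCCGTCAACAGAAATACATGTGCGCACGTCGCCCCCACCAGTCGTGATTTACATCTGCCGAACTGGCACACTCTCTGGTCGCAGGTGTGCTTATCATATAATACGGGGTAGTTCAGCTGGAGAAAAAGTACTCAGTAGGCCCCCTCTAGAGTTTCCACTGAGACGTCACCTTGCCGCTAATAGAAAGTTGAATGGCCATTGGATCTGGTGT
>SYNV4-1*01
GCGAGATTGATGCGGACTTGTACCGCGGCATGCTTGGGCGGCTGGCCGAGATGTTATAGCGCACTGTATGAACAGTCCGGTCATGGGGGGGACGCATTCCACGGTCAGCGAATGGTTCCATCCTTTACCCGTTGTTCGCCATCGGCTCTGGAGCATGTAGCGCAAGTGCAGACTATACCGACTACGATCAACTCCGGTTGGCGCAAATTTCGCCAAATTACATTGGCGGCTTATAAGCATCGAGCTGCAAAAGGCACCCAAGGCCCTAATATCGGGATACGTTGT
>SYNV4-2*01
GGAGAAACAGTTTCTGCTAAACCAGAGAGAATATCGCCCTCCATTAGAGCTAGCCGTAGATCGCAGAAAATATCGGCAGAGGCGGAACAGCCTGAGGAAGATCCTACCCGAACAAAGCACGTAGAGCGCCCGTCCTTATGTTGGGTGGCTTTGTACTCTCCTCATGCGCGAAGGTATGGGGGATCAAGGTTGACGACATATAACGCAAGAAATGAACTAGGTCCTTCGCAAAGACGATCTATCCATGCGGCGGATCGATTGGCCTGT
>SYNV4-3*01
CGCCACGGAAACAGCCAGAAAATAACTGCCAAGGTAAATTTCCCGTGCCATTGTCATGCTGGGGTGCACGGTTCTGTAAAGGACTTGTATGCGAGGGCACGGCGCGCAGCGTCGCGCTCACCGTCCCAGCAGGACTCGCGGTACATCCCATGGATGATAGGCTGTCCAACCCGCAGTCGGGTGCTAAGGAGCATCGATCGCTCCGGCGATGTACCTGACAACGTACGAGAAGCAACGGATAAATTAGCTGTAAATCGGAATGTTATCTGT
>SYNV4-4*01
GCTTCGAAGGTAGCAATAGGGGCCAATGATACTCCAGGAAAACGGCAAGGAGAACACCCTTGGAGACTGCACGAAAGCCTCCGAGTCGCATGCAAAGGTCCCGAATGTCTTGGTATCACACTTACTATTTGTAAAGACCCATCTAGCACGCATTCAGCACCGCTACGACGGGGCTTTGTCATTTCCTTACAGCATGAATCATCCTGGATAACAAATCCTAGAACGGTGCGCTTACTATCCCCGGGCCATTACTATTCCGATTGT
>SYNV5-1*01
CGTTACATCCTGTTGCCTGATGTGCATTCGGTAAATGGAATACCCTTAAAGAAGAGCCGCAGTGGTGCGAAACTATTACTTTACGGGTTTGGTACTTGTGTGCACCGTAGACGCAATAGCTCAAGTCGAGCGGTCCTGTTGACAGCTCACCACAAAGCGCTACTAGGCAAACCAATCAGAGTCCAAGACCTAGTGGGCTCGCTAGGCGTGGAAAAGATAAATCGCCTTTGGCTCAGGATCCTCACCCGGGTTATGCAACTTGCATTCGTGACTGCAGCTTGT
>SYNV5-2*01
TTCGACCTGAGGTCCTTCAACACCACTCTACTAATTCTTGAGGATTGGGTTGAAACCCCAAAACGAGGTCGCCGGGGATTACACCTTTCGGCCGCAATCAAAAATGAACGGCCTCTGATGACCCTTGGGCTTTGTTATCTAAGACGGTTAATGAAATGTGTGCTAGCCACCTATAAAGCGCCACGGCAAAGACCTACCTCCCCAATAGAGAGACTTTGTTCCAAAGTGTTGGTGATGAGCAAGGCACCGCTCAAAAATGCAATAACCCTTGTACTCATGATATGT
>SYNV5-3*01
CAAGATTGCCCTGATATGGTTTGGGAAATGACTGCAGGATCGCGCCTCGCAGTTAATCCCAAACTCGTAGTTACATACGATAGCATGGATTGTATACCACTAGTACACACCAATCTAGCGGGACCTATAAAGACTAAAAATGATAAGGACAGAGCCGGCCCGGGCCAAGATTGTAGTCTCGTTTTCGCGATTTGCTCTGCCCCCTTCCGCCAAAGGGTACAGAACCAGTGGCTGTTCATTGAGCATACTTATCCACAGAATCATCTGGTTCGCAGGCCGCTATGT
>SYNV5-4*01
TGGTGCCTTTGCCAATCGGAGATTGCGTGCCAATGCAACGGCATGCACGACCCCCGCGAACGTACGTCAACAATATTACACGGAGCACAGGTCCCAGGCGCATGGCGTTGCCGACCCCGCGAGCTGCTCGCGGTTGCGTGCCTGCCAACGGGCAGCGTGCGTAGGGGGGAGCTTCTAGACAGGCGACGAGTGTTTTTTCAATCGAATCGGAACCTGCCAGTCACAACAGAAAGCGCCAAAGTCTCGCAAAGTCCCACTTCTCATTGCTGT
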