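>IGHV1-1*01
GGGCGCGATGCACTGGATCCATCGTTAAGCTCGTCTTACCACCGAGTGGTCAACTTTGGTCAGTTCAGTC
CACTGGGAGCAATTCGCCGAACTTGGCCGGTGACAGTGCTGAGAAGTGCGCCGCGCCTTGATGTTAGCAT
GCAGACCGCAAATCCAATTGAGGTAGCACGAACGCTGCTAATCCCGAATCCAACGATATCGGTAACCGTA
CTAGTGATCGCCTATTCGAGTCCTTTGCCGACTGGTCAGGGCACATGGATCAGGACTGCCCTACCCTGGC
TTAACTGCTCTAC
>IGHV2-1*01
AAGGGGAACTCGTTAAAAAGCACCAAGGGCGGCCTACTCATTCGGCGCGAGGAGATGGGTTATCAGCTAC
TTCGCGTGCACCTTCTAAACCCGCTTGGCCAGATTACCCTCACCAGATCTCCCTATAAGTACAGGTCTAT
CCGCGTCTCGCGCGTAAGCACTGTAAGAGGACCTCTTAAGCTTGAGCTTCTCAGCTACTCGTCCACGGAG
GAGGTGTTTGATATCTATTCGGCTTCCCCCTACCTAGGCTCGACAGATAATAATTCCGATGCGTTCGGCT
GGGAAGATAAATGTATGGAA
>IGHV3-1*01
CCAATCCTCGGACTAGTTTTATCCGATCCGAGGGGCATAACACTCTCGTCGCGGGAAGGGCTCACGCGTA
GAGTAGACCTATCGCTAGCAGAGAATGTTCGCATTGTTATCCCATTTACATCCGTTAAGGCGCGAGTTTC
TTCAAGGCGCCGCGATCGTGCTACGTTAGAGTCGTTAGAAAGAGCACTTCTCAACCTAACCCCATTAGGC
GAACTGACCTGGGTCCATCAGGGTGATTACATATTTAAAAAGCCTATCTCCCCCCGAAGTAGCACTATAA
AGCTCCATTGCTCTA
>IGHV4-1*01
TTTCCAGTTAGGATTGACTTGCCTAAGGCTCGGGCGCTTCGGGTACCGCGGATTGCTCCCGTTCGCAAGC
TGAAGCGCGATATATATTACTCCGGCGCTACCGAACATACACCCGTGGATCTCGGAGGCTCATATGTCGT
ATCAACGCGAGGTAGCATACGCCGGATTTCCCTTCCTGACGAGCCGCTTGAGCATAAGAGAATTGACGAC
TCGACTTCACTTGAGCCGTATGGTAGACCATTTAACGGAGTGGCCACAGTTTTAATTGTGGGCACTCTGG
TGGTTAGTTTAATGTGTAATTAG
>IGHD1-1*01
GTTGTAGTCATCGCC
>IGHD2-1*01
TTATGCCCCCGATGGATGGATA
>IGHD3-1*01
GTTCCCGAAACGGAATAATGTTCCACTT
>IGHJ1*01
AAATTTTGGCGAGAGCCCAGGGAGCTCGAGGTCGCAAGGACGCGAACCGTA
>IGHJ2*01
CGTCGGACTGGCACGTCTTTAATTGCCTGCAGAGAAACTGCCCGGCACAG
>IGHJ3*01
TGTCTTGTGGCCCGGAACTGCCGTATCACAGTGGCACTTGAGCCGACGAGCC
>IGKV1-1*01
CATTCTATGCCCTATTACCCTGCCCCCCGACAACTGCGGCACATTTCCAAGTCTTATTTCCTGGCGCAGA
AAATCTGGAATGACTATATACCGAAAAGGACGGCTGCGAGAACGAACCTAGAGCTGACCTTGACTCTCTA
CGCAAAAAATTCTGACACTTTTCTTGGAACCCGTACTATTATCATGACGACGCACGAGCTACTACGAAAG
TCGGTTGTACCGGTACGGCGAGGCAATACAGCCTCTATGAAAGGGAAAGTTCCAGGACGTAAAAGAATAG
GTACCTCATGCGCTG
>IGKV2-1*01
ACCATTGGATTTGTAACGGGGATTCAAAGACGCTTTAAACTTACCCAGGAGAAAGTTGAATATATAGTGT
ACGGACACCCGTCTACTGTAAGTTCTGTTCCGCGCGACCTTATGGTACCAGGCCCGATCGACAGACGAGT
TCTCTTGTGGACATATGTCTCACGCCGAACGTTTCGTGTACGGGGACTAGAAGGTACCACCTGGGCGTGG
TGGCACCGCATCGGTTTCGGGCTCCAGAAGAGTAGTATGCTACTAAGTCCAAGAACCCTTTTCAGTTACA
AGGGCTGCCAGGC
>IGKJ1*01
ATGTCTTTCCGACAGATGCACCACGCCGCAAGGCTTGGAACACT
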