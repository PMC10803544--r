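>FCGR1
ATGTTGTACGCGAACAGCCTCAACGAACACACGCTCTGTTTTCATTGTTCCTCACCCAGAATTGCAGTGG
AAGCCAGTCGGGATCCTCTTAGATTCCGTCAGGCACGCATGCGTCTGTGTCCGCAACGTTTGGTTTGGAC
CTTGAGCTTCCGGTTTAATCTTCTAGCTCCCTCCCGTAAGGATCCAACATTGTCGCTGCTTATCGCGCTG
CCGTGCTGGTTCCGTTTAGTTCCCCTACATCTTGCCCCGAGGCTATCTACGGCACACCTATCGTCAGTGA
TTGACTCGGTAGGTCGGAGAAGACCCGGAGTAGAGAAACATTCTCCTGGTACGGCCGAGTTCATCCACCG
AGCTGGTGGCAATTCTTACTTTGTCTGCCTCTTGTGTCGTACGACAGACTTGGATACGTTCCTAGGCGGG
GTTAGTCAGCAACGCTCGTTGAAGGTAAATAAGCTCCTTTTTTATAGAGCCTCTGCGGACGGGTTAATCC
AAACGGGTTATATCGAGGCGGGCTCCCAAAGTGCGTCACGTGCGTCGAAGCACAGAGGTGTCCTCTTTGC
TATATCCGCTGTAGTCGGTTGTCTTGTCATGAACCGACACCCGGCTACCGACACTATTTTCGTGGGGCTA
AAAGAGGAGAATGGAACCAAGCGGGCTATTTTCTTCTACAAGCGACAAGACCCGACCGATTCGCGACTCA
CGCAGGGCATGCGCTTAGACTTGGTCATCACTTCGCACGAGATGATACACGGGACAGCTTGCGTTAGTAA
ACGTCTATACGTATCGATTTGTATTGCGATGGAATGTCTTTCGGGCCAGCGGCTCGTGGAAGACCGTATA
CATCACAGTGGAGTACAGCGACCGCTGGCAAGAGAGTCGACACTCACAACAAACACTTGGTCGCGCACAT
TTCATATTAAGCCGGCCAATGTATCGGCCATATGCGCATTTCCACCAAGTCCTAATCTCAAGTACCAGGA
AGATCATCAGCGTGCTTTTCCCATCGACCGGCTTGGGTTGGTTGGCCCACTTTATCAGTTACCTACGCAT
GGTAAGTTTGGAACGATACAGGTAGAGGATCTGATCAACTGCGATTGCTACTGGCTGTGTGTGCGAACGT
TGTAA
>FCGR2A
ATGAAGGCTTGGAATCTTAAGAGCCACAGGGAGGGCCGGCAAAAGATAGTGTGTACTCTCTGTCAGTCAG
TCCCCGAGACGGCGGATGTCCCATCTTCCTTATTTATCTTCCCGGGTCAACCGTCCTCATATCCGGCGTC
CACTTGCGTGTATATACGGACTGGTTATGAGGGACATCCTTGTTGCTACGATGTGGACTTAATCCACCCG
CATACCTGGTTTAATTCCTACCATATTATGCAACATAGCATTTATCCCAGCTTTTTGATGAGGGGCAAGT
GTTCCACAATATTGGTAGTGTCATGCCTTGTACAGAAGTACTTGCGAAAGTACGCGATTACCGCGTGGAC
ATGGACAAGTTCGCATATCAGTAGCCCGATTAGGCGTGTTGCGGACGAAGAGCCGTCGTCTCACCCACAC
GCATTGCAAATTCCTCGTCATAGGAAGGTAGGAAAGCTGGTATGGGCATCGCCCGCAAAACGCATCAACG
GAAGCCATTACAATCGCATGGTTTGGGAGGTCCAAAAAAGCCACGACCCCCAGGCAAGTTTTAGCGCTCC
TCTTTATCTATGGGAGGGACTAATGACAGCGACAGCCCAACACGCGGTTCACTTCTCATATTGCTCTTCG
TTATGTGCCACACCGGTTGTGTATCACTCGTCATTTAGCGTCCTAGTTGAAAGTCGTTGTTATCGATCTT
TAGTATCAATCTTCGAGGTTCATTTTGTTCTAAAGACTAAAACCGCTACACTGGTCGAACATCAGTTCCA
TCCAGTTGGATGCACCCGTTGTCACAATATGTGGGATCATAAAATGGCTTTCATACACAGCCTTGCCAGC
GTCTCGTTGAATGGCAACGTGACGATTACTGTCTGGTTATTAATTATCAGTAAGCGTCTCTTCGTCATGG
TATCACTGACTTGCCCAGCATAA
>FCGR2B
ATGGTGCGTGATGAAGCCCCACCTCGAGTAGGCGACCACTACATGGGACGGTCGAATCCCCCTAGGTGGT
CCCAGGACCTTTCCAGATGTACCGATCACGGTGCCCTTCCATTGCTTCTTCAGATCCTGTGCGGAACAAT
ATGCCGTGCCCTCCGGCCCCTAGTATACGAAGCCGAGAATCTGCAACGTTTACAATGCCTAGAGAGAAGA
TACCGGATGTTCGCAACGAACATCATCAAACCACGTCACGCGCTATACCAGATTCCACTCGCTTTCCCAG
GCTTCCGAATAGATTATGCGCGCGAACCCGCTAGGGGTGCTGTAGCCGCGCTACATCCTGACAGCCGCTC
GTGGCAAGAGAGTGCAAAACCTGTTTGGTTAGAGGCACCGACGACGGCTCCACTCTGCGCCTGGAGCTCG
GTAAGCAAGACTCCTTCCGTTAACACATTACCCCAATGGCTTGGCCAGTTGGGAAATCTTATGACCAAAA
CTACAAAAATTACTACTATATCTCTACCCGACAGGCCGACGAATCAGAACATTCATGGTGGTCAATCAGG
AAGCCTGAGGCGCCGATACGTCCACTTGCTTCACAATGTTCCTCATATGGGGGGTAGATTTACCCCTACC
GTGTATACTCTTTTAGCTTTAGGGCTGCCAGACAATACTCGGTATCTGAACCTTTCGTTCATCCCATCCT
CGAGGGATTGCTATCAATTTGATGGAACAATTCGGCCCCCAGTATCGCTATACCGCGTGTTAATACGCCC
TTTCCCTGTAAACATTAGCGGTGTCCTTTACCAGACCTGGATGGGACACTTAGACTCCATCGGGCCGCCG
CACGATCCAAAGCCTTTGACTAAGGAACCTGAGGCCACCGCTTTCGTGTACCGCAGCCGGGGCTGGGGTC
TACATAAAGAAGGGCAGAGATAA
>FCGR3
ACACTACTCTCTCTGATCACCGTGTGTGGGTTCTTTACGGAAGTTTATGTAGGATGGGCCACCGTCGCGG
AACTTACCGAAGTGAGTTTTATGGCCGTGGTAATCAGCCCATACAAGTGTACAGTTTCAGTTATCTTAAA
TTCTTGCTGTGGCCGGACGATACCCGGCGGCAGAGTTTTCGACTTGGACTATGGGAGAACCGAGCGAACG
TAAGTCACCGCCTCTGGATCCGTGAGGCTATACTGGGGACGGTTCGATCCCTTGAAAAATTGCAGCGCAT
ACACTTACACGGAGCTGGATCATACCAGCAGCTTTATAGGACTGTGTTTTCGAAGTTGGAGTACTCCTTA
TCAAAGCACACGCTGAAAACCGAGGCATGTTCCCAGTCGCGACTCGTATCTGTATGTAAACTACCTGTCT
GGCGAATAATGGTATTGAGGCTACCTGGGCGAAACTCAGTGCAGCTTCAGGGATCCTACATTGTATCTTC
GGCACGACTAGCTTTGGTGACGATGGTCTCCATTGATAATTTTTGGCTCCAATTAGTAACTCAATTGAAT
CATAAGGTGAATAAACTGACGCACCAGGCCGACTCTTCGCGTTCCAGTCTGAAGAGGGCGACGACGCCCG
AGTCGAAACAAGTTACTCAATTAAGTATGAGAACCTGCGCTAATGATTTCACGGACATTGCTATTGGGCG
CGTATTGGTAGAGACGTGGCTGTTTCAAACGTCAGTGGCCAAAGAGGAACACACGGATATTCAGTTACGT
TGCTTTACTTTCCGGGCCTCTCAGGCTTTGGTTGGGTGCTTGCTCAGGGTATGTCATGAAGATAGAATGT
TCTTCGTGCGCAATCAAGTTCGCCCCGAGTATGGGTCCATGGTGCCCGAGCCCTAA
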