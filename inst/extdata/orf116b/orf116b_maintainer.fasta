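>orf116b_locus_maintainer
TAATTAATTAATTAATACCCCTCTTACGAGGCTATTTAGATAAAGAACTTGGAAACTAATATTAAGACAC
ACGGTTATAACCCCTAATGCATTTACTCTACCAGTGTCCAGAACTGTGGATCTTGAAAGGTCAATGGAGC
CAGAGAACAATTGATCTATCAAACATTGAGGGTTTATACTTATCATGTGTCCTATAATGGTCATCTTCAT
ATAGCCTTAGTCTATCGCTCAGAAGGTTGCTACATGATGCCATACACATATGTTTTACTTTGCTGCTATC
GGACGCTCTACGACAATTTTTGTCAATTGGGCCAGTCAACCGATATTTCATGCCGTTTGTAACCCCTGAA
AAATGACAGTAAAACTTGGGGCGGGTATCCCAACGTCTAAGTTTAACTTAAGCTTTGTGTACTAATATGA
GACAGAAAGTGTGTGTAAGCTAAGCTTCCAGTAATCCATCCATAGTACCATTGTAACCTCACACATTCCT
GTTCGTTGTCGCATACTTACGTCACGCATGATTAGCGTAAACTTCTGTTGCGGCCTTTCGAAACTCACAT
CTCCGCCAAGGATCAGCGGGTGTCGTCACGACACTGATAAATGTGGCAAAAGGTTCCGTTCCCCTTAATG
GTGACAACGGTAAAGCGCCATAAAAGTCGTCCGCATTCAGTGTCAACGGTGGTGGTGTATTCGTATCGGA
TCTCGTTAATCATCCTCAAGGCAAAAGGTAGCGCATTGCTCACGAGAGTTCCGGGGCTGACTGGTGCAAG
TTTCTCTACGGGCGCTATCCATGAGAACAATAATCAGAGCGACGTGTTGTATTCCAAGAGCAAGGCTTCC
TGTGGAAACCATCAAAAACGGTATTCAACTTCATCGCACTCGCAACGACCGTGGAAGACGCATAATATAG
CGTCTACAAGCCTCGGGACATCTATCCATATCCAGGATCTGCACGCTATTCGACAGTCTTTCTTCGTGGC
ATCTCGAATTCACGGCTGGGATCTTACTTTTGAGGCAAATGAAAAATACAAGAGAACCGTTTGTGCATCA
GCGCGTGACTACAGTATGTTGCTTTTGAAAGCAGAGGTGTTTTTACATTGTGCTGTATGCTCAGGAGCGA
TTCGCCACGGGTTAAGCTGCGCGCCGCGCATCTAATAATTAATTAATTACACAACACGAGAAAGGAAATA
TCTGGAGAGGCTTTCAGCTCGAAATAAGATAGCAATAAGGAAATTTAGACGCCTATTAAAGGAGTACAGA
GTTATTACTGAATAGACGCCTTGTATGGTGCACATGCTGAGTAATCCTCATCCGGCCGATACGATTTCTC
GTTGCATTATAAATGGCGACGCATGTGGTGTTAGACTAGCAGGACTGTAGACCTGGCTATTAACTATATC
GTGGACCAACTTCCGTGATGATATTCCTGGGCGCCTACAGGCTCTAATGCTGTATTCATCTTGTATGCAT
TCGTTGAGAGGTCAATAGTCGGACGGTATCTGGAAGGACCGCCGTAGGCGGGTAATGGATATTCCGTTCG
AATTTCATCGTTTAAATGATGATGATGATGATGATGATGATGATGATGATGATTAAAGAAATTAACTCGT
TTAAGTGCATTACACCACACGAAGTCAATCTTCGTCTCATGCGTTCTTACCTAGACCTAACATCAGCAGC
GACAATGGACGAGTTATTTATAAATCACGTCCCACGCGTACGTGAACAATGTAAATTACATCTAGCGCGG
ACTCCTGTAAATATACACGGCAAATCGAGATCCTTAGGTGTTGTTCAGACCTCTTTTCACGTTAAAACTT
GGCTTTTCTATTCGGAAGTTATTGTCTTGCAAATCCTGGCCAGTCAGTTCAGAGAGACTCATGTGAGAAT
GGGAGTGACACGTGTAGTATTGTTAATTTTAGGGGTCATTGACATTTCAAGAATCGGGGGGTCGACTCCG
CAACGCTTTAGTTTGGTATCTTTATCGAGCGGTTTGTCCCGTTCAACCCACCACCCCTACCCTCAAGTTG
AAAACGAACGACCTCGCCGTGAGTTTCACACTAATTTGCCGGAAACAAGAGTCGGTTCTCCGCCCAGATA
CGTGCGTTTCCGAACTTCCATCGACCTAGTATTTCCTCGAGATTCAACGTCCTCATCCATTCAGTTATAC
GTCCAAGCGACCCGCGTTAGACGGCGAAGATTCGGATTCCTTAAAGCCCATTCAAAAACATGTATATTCC
TTCCCGCTCGGCATAGTAATGCAATCGTGAACCCCTACTGCTGCAAGCTCATTGACCCACAAACGCTTTT
ATGCCCAGGGTGTAGGAAGGGGGCGCTTTCCATAGACCAAGGAAGAAATTCGAAGTACCTATTTATTAAA
GTCGCTCGAAAGGATACGCGCAGTTCGACTCGTGTTTTGATTAGTATCTTGGTTGTCTATAGAACTAGGA
AACTCTTGCTTGAAGCGGGATGCCGATACTCGATCTTCCGTCTTTGTGGGTGGTTCTTACTGTTACATGC
TAGAAGTGATCCATTTCTGCTAACCAATTGGTAATAATTAATTAATTACAGGAAGAAACAAGCCAGTTGA
GATATTGAAGTACTATCGAGATAAGCACCTTATAGCCCATTCCAGTAATCAATATAATGGGGGCAGGCGC
TAAGCCAGAAAATTGGGGTACAGCGGCTGTAACCGTCGTGCGTATGTAGTTGAAAGATAGTCTTACAACT
CCTTTGGGCGGGTATTGTGGTTGACGGCGCGAGACCACGCTAATTTAAGAAACCAATGTATTTACTTATG
CTGGCTTAAACTGCAGCATTTATCGAAATCTAGCGAGCTTCGAGGACAATGGCAAACGGGGGAGAGACCG
AGCCTACACTCCGTATGTTGTAATCGGACCAGCCTCTTAGAGTTATAGATGCCCTACACTCTTGGATGCC
CTGCATCACAAGCAACTTAATGCGATGGGCTAGTATTGCACCTAGGGACACCCGTAGATTCGAGCATTGC
GCGAGAGTAGCGATTCCTAGGGTCTGACCTCTGTATACTACTAAATACACTAAAAAGAATCTAGCGAGAA
GGTGCGTGATATGCAGCATGTATTGCAAAACTGTACAGATCGCATCTTTACTACTAGGGATAGCGAGGCG
TGTGCTCTAATCAGCAGGACTTTGCCCCTTTCCTAAAATGTTAATGGACTCATAGCCGCGCCTCCATGCT
ATACTGGTTCCCCAATTAAAATTCCCCGTGACTCGAAGCGCACGTGCTCTTCAGTTTACTGCACTGCTAG
CTCACTGAATATGTAAATAGACGTCTCAAATAATGATCTACCTTGGACTCAGCGCCTAATTCTCCGCGCT
CTGAACCAAATCAAACGCTTCCGGTGTTAGAACGATGACTCTGTAAGCCCTGTAAGGTGTCTGAAACTTT
TAAGAGGAAAATGACTGATGTTCCGGACCTTTCCATAACTGCAGTCTTTTATCCGCTAAAGATTGTGTTA
CCAAGTATTGAAATGGTATTTAGCCCTACCCGGAAGGCCAAGCAGGGGTAGCACCCGAACCAAACCGAAA
AAGTGGATTCGGTATGTAATAGTATTCCCCGGGAGTAATGATAATAAGTTTTGGGCAGGATAGCCGTTTG
AAAGCATACCGCGATACCTGGCGAATCTCCGACGACTCTAAATTCGTCGTTTCATCCCTGGGCTAGTACC
GTTCGGATAGTTAACAGTAACTGCCTGTGCTAATTAATTAATTATAATTAATTAATTAACGAAGGTTTTC
GCGTGGACTGCTCCATAGTTGGGGCTGTTCCTGGTGGCAATAGTATTTTTTAACTTAAGACGACTATAAA
CACTTGGACGCAGAGCTACAAATACTTTATTACTAGAAATGCTTGGTTTCTTATAATGCAGGTTCAATTA
AGTCCGGGGACGTTTTCGCTAACTCTCTGATATGAATCTATACGGCACGGTATTCTTAGATACACGACGT
TCCCGGATAGAGTATCATGGGTATGGATTCTAACAATGGTTGCTCTCAGAGCGAGTTCCCGCAGGTAACT
GGTAGGCGTACTCTATGGTGAACTCCCAGGGTCCACGGAGTTCCTGTTCAAAAGACGACTAACACTCTAC
AGGAGCTGGGCCGAAGATTTCCCTTGTGGGCAATCCGCGGAGCCCTGCTACTGTATCTTGGGAAAGAGTG
TGCTGTCCGTAAGATACCGCTGTAGCCTTGAGAACCACTCCCTTAACGGTTTTATTATCTGGGGGCAAAA
TGGCAACTGATCAAACGCACCCACGATTTTGTGTTTTAAATTTCACTATACTTAAGACATGTCTATAGGT
ACTTACTGTGGGTTAGAAGTAGCGATAAGCCTAATACCGAACCACCTAATCGTGGCTGTGGGGACCAGTG
GACAAAAAATTATTGGTAACTATCCCATCCAAGTAGACTCTCCA
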