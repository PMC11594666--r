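>orf116b_locus_cms
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
TTCGCCACGGGTTAAGCTGCGCGCCGCGCATCTAATAATTAATTAATTAACGTGCAACGGATTACTAGAA
ACTCCATAGGTACTACGCCTCGATTTGTCACAACCTTCTGATTAAGTGAGACCGTTTGTAGCGGTGCCGT
GGGGATTAACAAGGGCAATTTACATCCAAGATGAACACTGCAGATATACTACGCTACAGAGCCCTAATTT
ATATTTCCCTAAATGTCATCTTCATCTTCATCTCTAACTAAGCTTCATTCTTCATCTTCATCTTCATCTC
TACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTATCTTCATC
TTCATCTTCATCTTCATCTCTAACTAAGCTTCATTCTTCATCTTCATCTTCATCTTCATCTTCATCTTCA
TCTTCATCTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTC
TATCTTCACTAACTAAGCTTCATTCATCTTCATCTTCATTAAATGATGATGATGATGATGATGATGATGA
TGATGATGATTAAAGAAATTAACTCGTTTAAGTGCATTACACCACACGAAGTCAATCTTCGTCTCATGCG
TTCTTACCTAGACCTAACATCAGCAGCGACAATGGACGAGTTATTTATAAATCACGTCCCACGCGTACGT
GAACAATGTAAATTACATCTAGCGCGGACTCCTGTAAATATACACGGCAAATCGAGATCCTTAGGTGTTG
TTCAGACCTCTTTTCACGTTAAAACTTGGCTTTTCTATTCGGAAGTTATTGTCTTGCAAATCCTGGCCAG
TCAGTTCAGAGAGACTCATGTGAGAATGGGAGTGACACGTGTAGTATTGTTAATTTTAGGGGTCATTGAC
ATTTCAAGAATCGGGGGGTCGACTCCGCAACGCTTTAGTTTGGTATCTTTATCGAGCGGTTTGTCCCGTT
CAACCCACCACCCCTACCCTCAAGTTGAAAACGAACGACCTCGCCGTGAGTTTCACACTAATTTGCCGGA
AACAAGAGTCGGTTCTCCGCCCAGATACGTGCGTTTCCGAACTTCCATCGACCTAGTATTTCCTCGAGAT
TCAACGTCCTCATCCATTCAGTTATACGTCCAAGCGACCCGCGTTAGACGGCGAAGATTCGGATTCCTTA
AAGCCCATTCAAAAACATGTATATTCCTTCCCGCTCGGCATAGTAATGCAATCGTGAACCCCTACTGCTG
CAAGCTCATTGACCCACAAACGCTTTTATGCCCAGGGTGTAGGAAGGGGGCGCTTTCCATAGACCAAGGA
AGAAATTCGAAGTACCTATTTATTAAAGTCGCTCGAAAGGATACGCGCAGTTCGACTCGTGTTTTGATTA
GTATCTTGGTTGTCTATAGAACTAGGAAACTCTTGCTTGAAGCGGGATGCCGATACTCGATCTTCCGTCT
TTGTGGGTGGTTCTTACTGTTACATGCTAGAAGTGATCCATTTCTGCTAACCAATTGGTAATAATTAATT
AATTACAGGAAGAAACAAGCCAGTTGAGATATTGAAGTACTATCGAGATAAGCACCTTATAGCCCATTCC
AGTAATCAATATAATGGGGGCAGGCGCTAAGCCAGAAAATTGGGGTACAGCGGCTGTAACCGTCGTGCGT
ATGTAGTTGAAAGATAGTCTTACAACTCCTTTGGGCGGGTATTGTGGTTGACGGCGCGAGACCACGCTAA
TTTAAGAAACCAATGTATTTACTTATGCTGGCTTAAACTGCAGCATTTATCGAAATCTAGCGAGCTTCGA
GGACAATGGCAAACGGGGGAGAGACCGAGCCTACACTCCGTATGTTGTAATCGGACCAGCCTCTTAGAGT
TATAGATGCCCTACACTCTTGGATGCCCTGCATCACAAGCAACTTAATGCGATGGGCTAGTATTGCACCT
AGGGACACCCGTAGATTCGAGCATTGCGCGAGAGTAGCGATTCCTAGGGTCTGACCTCTGTATACTACTA
AATACACTAAAAAGAATCTAGCGAGAAGGTGCGTGATATGCAGCATGTATTGCAAAACTGTACAGATCGC
ATCTTTACTACTAGGGATAGCGAGGCGTGTGCTCTAATCAGCAGGACTTTGCCCCTTTCCTAAAATGTTA
ATGGACTCATAGCCGCGCCTCCATGCTATACTGGTTCCCCAATTAAAATTCCCCGTGACTCGAAGCGCAC
GTGCTCTTCAGTTTACTGCACTGCTAGCTCACTGAATATGTAAATAGACGTCTCAAATAATGATCTACCT
TGGACTCAGCGCCTAATTCTCCGCGCTCTGAACCAAATCAAACGCTTCCGGTGTTAGAACGATGACTCTG
TAAGCCCTGTAAGGTGTCTGAAACTTTTAAGAGGAAAATGACTGATGTTCCGGACCTTTCCATAACTGCA
GTCTTTTATCCGCTAAAGATTGTGTTACCAAGTATTGAAATGGTATTTAGCCCTACCCGGAAGGCCAAGC
AGGGGTAGCACCCGAACCAAACCGAAAAAGTGGATTCGGTATGTAATAGTATTCCCCGGGAGTAATGATA
ATAAGTTTTGGGCAGGATAGCCGTTTGAAAGCATACCGCGATACCTGGCGAATCTCCGACGACTCTAAAT
TCGTCGTTTCATCCCTGGGCTAGTACCGTTCGGATAGTTAACAGTAACTGCCTGTGCTAATTAATTAATT
ATAAATGTCATCTTCATCTTCATCTTCATCTCTAACTAAGCTTCATTCTTCATCTTCATCTTCATCTTCA
TCTTCATCTTCATCTTCATCTTCATCTTCATCTTCATCTTCATCTTCATCTCTACTTCTACTTCTACTTC
TACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTACTTCTATCTTCATCTTCATCTTCATCTTCATC
TCTAACTAAGCTTCATTCTTCATCTTCATCTTCATCTTCATCTTCATCTTCATCTTCATCTCTAACTAAG
CTTCATTCTTCATCTTCATCTTCATCTTCATCTTAATAATTAATTAATTATAATTAATTAATTAACGAAG
GTTTTCGCGTGGACTGCTCCATAGTTGGGGCTGTTCCTGGTGGCAATAGTATTTTTTAACTTAAGACGAC
TATAAACACTTGGACGCAGAGCTACAAATACTTTATTACTAGAAATGCTTGGTTTCTTATAATGCAGGTT
CAATTAAGTCCGGGGACGTTTTCGCTAACTCTCTGATATGAATCTATACGGCACGGTATTCTTAGATACA
CGACGTTCCCGGATAGAGTATCATGGGTATGGATTCTAACAATGGTTGCTCTCAGAGCGAGTTCCCGCAG
GTAACTGGTAGGCGTACTCTATGGTGAACTCCCAGGGTCCACGGAGTTCCTGTTCAAAAGACGACTAACA
CTCTACAGGAGCTGGGCCGAAGATTTCCCTTGTGGGCAATCCGCGGAGCCCTGCTACTGTATCTTGGGAA
AGAGTGTGCTGTCCGTAAGATACCGCTGTAGCCTTGAGAACCACTCCCTTAACGGTTTTATTATCTGGGG
GCAAAATGGCAACTGATCAAACGCACCCACGATTTTGTGTTTTAAATTTCACTATACTTAAGACATGTCT
ATAGGTACTTACTGTGGGTTAGAAGTAGCGATAAGCCTAATACCGAACCACCTAATCGTGGCTGTGGGGA
CCAGTGGACAAAAAATTATTGGTAACTATCCCATCCAAGTAGACTCTCCA
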