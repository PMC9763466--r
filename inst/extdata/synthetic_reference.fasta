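>reference
CCTGCACTCAAAGCTCGTCTTAATTTTGGAAGTAGCATAAGAAAGTCAATGACGGCCCTGCTCGTCGATCGAGTGTTGGG
GGCCTTGACTTCGGGCTTAAGCAGGCGGGCTCTGATCTAGTGGTCCATCTTTCTTTAGGGGGCCCGTGTTTTTGTGGTCT
GTTTATATTTAGAAAACTATCGTCATTGCTGAGCTACGCAGTATCTATGATGCCCGAATTTCTCTTCACAGAACGTCGGA
ATTTCTACCGGTCTCATGCACGTACTCATTAGGTGCAGCAGTTATCGGTGTAGTTAAGATTATGACTGCGAGTGTATGCA
ACCCCAATGGTGTAGCAATGGGCCGTCCACTTGTCGGAATTGTGATAAGGGCTTACCTTATCAAGAGCGTTAGTGTTCAC
GCGACGCACGAGTTCTGGCAGTTCCGGACCCGCAGGGACTAGCTGCATATAGAGAGTGATCGTTACTGGCATACAGCCGT
ATAGACTAAGAATATCGACTACGCCGAATGGCTGGATGCTAGTCTCCATACCAGGGTAGAGGAAACTAATCCGCCCTAAG
CCCTTGCACGTGCTGGAGACTGCACGCGGGTTTTCTCTGGCCCTTAGACCCGGCGACCGCTTACGTGCAAGTTGAGGCGC
GATATTAACGTTCCGTTCTAGGACCGCCCAACATCTTGGGAAGTATACCGTCACGTTGGCGGGCACGGCCGACGTGATTG
GTCCATTCAGATTACCCATACTGGACAAATTAAAATCGGCCGTACCCCATATAGTACAAGCTAGACAGCGGTTAACTTAC
AACACTCGGCCAGTATATGGTCCTCCACTACAGGTCCTCCACAGGCACAGCCGTACGGGTCATGACTCGAGCAGGAAGGG
CGGGCACCCGCAGCCAGCCCCAAGACCAACGGCAATCAATCGTGTCAACTCTAATGCGCTGACTTCGGTGTATGCTGAAC
GACTCTCTACAGCTGACGAAGCACTCACCGCCAAAGGGGTATTGTTACCGTATCGCGCCGTTACAGCCATCGAAAATCTC
CGCCATATAGTGAAAGATTGCTCATTGAAGCCGTCCAGTCCTCGACCGTTCAACAAGCTTAAGAAGCAGTTTTGCTTTGG
AACCACTATAGGTGAGGCGCACGAGTGGATTAACTGCGATTCTCAAAACGCGGTGCCAAGGCCGAGCACCCAGGCAGACG
CATATCGTACAGAGATTCCGGAGCGAGCCCACACTACAGCCGATCTCCCTTATCAATTCTACGTAAGATTAGTCCATGGA
GACATGCTAGAGACGGCGGGCCATCTTCCGAAAGTTGTGGGTTTCTGGAGCGGGCAAAAGCACCTAAGTAGAGTGTATGG
GGTGTCGCTCACCGTCGGGTCCGCTATGAGACCAACGTCATCTGGAACCGGACGCTCACCAGCAACAAATCCCGAGATTG
ACATTAATTCGCAGACCACATATGAATTGAACGGACCAATAAAAAGCTGGCGTCAGTCCAGTTGGTTAAACCGCGCATTA
ATTTTGAGTACCCTTGATGGAGGCGCATCCCCTGTTGCTATTCAGAGATTTTCGGAACACTCGGTCCAGTGTATCACCCC
TTCAGCGTGGGCGACACTGGTCACTTTTAAAGGCCGCGTCGAGCGTATCTCCGAGTACGAGGGCAAGCCAACGAGAGGCC
GTGGGGCGGTCCTTCCTGCTATCCCACAAACTCTTTATGCTACGCGCATGACTCCAAAGCATGGCCATATCAAACCTCCC
ATTACTGCACGCATTGCAACTGGGCTGAATGTACCTTGCGGCTCTGTCCGGAGTCTTAGAGCGGGGATAAACATGTAAAA
GCAAGAGGTGCAAAACGGATCGCTGACGTATGACTAAGGGCATTGATCTCTTTTCTGCCATTGCCATCGATTCGGAACCC
ACATGCACCGCTTTATTTGCAGAGCTCATGCGAGGGTAGAAATGTTCTAACTTAATGCGTATATGTAACGCGTACAAACA
GTCACAGTTCAAAGAGAATTGGCCCATTGGTATGCTTGGACAACGGTCACATCTCAGAGCAAAGGTGTAATACCACAGGA
CCCCAAGTTTTATAACCGAGTATTAGTAGGAAGTCAAGAAGGTACCAATCGCACTCAGAAGTGGGTCGTCACCCAGATGA
AGTTGGAACGGATTCCGACCTATGTCGGCCGCCCCTCCTCAGCGCCCAGGAACTTGATCAATATGAGGCGCGTTAAATAT
AATAAGATAGAAACAGGATAAGCACTCGCGGGTTCTGAGAATGAGCGCTCTCCCCGGAAGTGTCGGCACCGTTTATGGGC
ACTAGATACTCTAGCTAACAAATCGTTATAGAAGCTGTCACGTGGTATAAGCTCATAGCTCACGGTTGTCTAGGGGCTGA
AATTCCTCAGCAGCGTGGACGGGCCCACTGGAGTGGGCAGGTGGTTCGATTTAATTTGTTATATAGGACTGCTCATAATG
ATAGAGAAGGGGACCGTGGCGAATAGTAAGGCCGCAACCGTGAGCTATTGGCTTTCCATTTGTAAGTTTTCAAAGAGGAA
GCGGTCCAGTCGGTCGTCAATTTCCCTCTGCAGGGAACGACGTGGTACCCCCCGTCAGGCGATGGGTAGCGATGTCCTGC
CACTTCGCGTGACTGTTGTCTTTACTCTTTCTTCCAATGTCGCTACTGAGTCTATTGTTGTCAGTTGGAATCGACACCAT
AATAATACCGATTGAAGTAATTCGATTAGCTTTAAATCCGAGTCTGCTCTCTAACAGTCCACTCCCTCGACCCAAAGAGA
AACATCTCACTAAGGTCCGATCTTATGTAGAAACCGGGAACGGCGTCTCAGTGCTACATGTTTCGGATGTAATAGCCGGA
TTTCACACCATATTTGTCGAGCCAAAAGACTTAGAAACACACCTATACACCCTAGATTTCATATCGTTCTTCGATCTGAT
TGCGTCCGCGTCACAGGCAAGGCAACAGCGGTGGGGGGATCGAGGCGGGGTGACTGTATGGGGGCACAGTCTAAAAAAAC
TGGCAGCCGATGCCCTGCTTTCGCAAGAACCCATGTCTACGTATCCTATCCAAGTGACCCTACGAGCGACCGACGGTGGC
TTTTCGGGGACCCGGATGCCACCCCAACACGGCTATTCCGGTAACATGTACTCGAATAGATCAACTGGAATAACTCGCGA
CCCGAAGGATCGCTTGTCTCTCGAGCCTGCCAACTTACGTCTCATGGATAGGTCCGATCTGACTGCCGAAGAGCTAGAAC
AGCGTTGTCCCTCTGATAGGCGCGAGGTGAAAGTAAGCTTTTTACCTCAAGGGGCAAACTCAAGTAGTAGCATCGAAGTA
TTTAGTGTAAGATTACTGACCCTTAACTCTTTAATATTTCGTTCGACACTTTATTCATGCCTCAAGGTGCGGAATTCGTC
TTTTTTGACCACAGAGGCTGGGCTTCCCCAAGTATCAGAAAATCAAGTCACCACAAACGTGCGGGGCTACGGTCTCCCAG
ACAATCTCAGGACAAGATGTATTCATCTCCGGCGAGGACCGACGATAGGAATTGAGTTTAGAGATCCGCCAATTATACTT
GGCACTCGTAAGTGGCCTATTAAAACTTCGAAAACGTACCAAAGCAATCAGGAGTAAAAACCAGACCCTGCGTACCGGTT
CCCCGAGAACCTGATGAACCCGGGGCTGCTGCGGGGGCGGGCCAACAGTGTTCGGGAGTACGGTCGCACGACTCGCTTTC
GTTAGAGCCTACTATAGAGTTTTGAACAAGCCGTCTTTCCTAGGTAGCCATCATGTAGCCCCATTCCAACGGAAGCCTCG
CCCAGAATATTGCGCGATAGCTGGTTGGCCCGCACTACTGCCCTAATACTGTGATGGATCATAGAACTTGCGGTCCCCCT
AGACAACGCGTTGGTGTGTGAGGAAGAAAACACAGGCCGAGGTCAGTCGCAGGAGCACAATTGTCTTAAGCGACGCGCAT
CTCTGCTTGATAGGCGTACCTTTTGTACATCGTGACCTTCCAGAGTGCCCGATCGTTCGCCCCTTTTAACGCAGCCCATA
GTTATAGTGAAGCCTCTGTAAACAGGCCAGAGGCATTGTTCAAGCTGCCCGTGTGGACTTATGGATCATTCACGTTTGAG
CCCATTGACTCCGACCGTTTGAGGGGGGTGTTGCACGGACCGTCCTTCTGGCACAACATGAGGAGCGGCATAACCACACC
CTATACCAGCCTGCGGAATGATGTTACCCGAAAGGGGGGAGGTGGAATACCTGCGGTAGTTCCTAACGCGCGAAAGGGAG
TGATCTTGTCATGCGTCGCCATACGCCCGGCCCACGGCTGTCCCGGGTGCCTTGAATATGTTTCTAGGCAATCTTCAAAC
GAGCGTGTGAGCATCGATGATACCAGCTGTTTGATTCACGCGGGGCTATTCCCTTTTATACCTAGCCGGGAGATAGGACC
TGTGAAGAACTGGTGGCAGTGGGTCCGACCACGCCATGGTGCGGCAGATCGCAGTTAATCCACTCGTGCGCCTCACCAAT
AGTGGTTCCAAAGCAAAACTGCTTCTTAAACTTGTTGAACGGTCGAGGGCTGGACGGCTCCAATGAGCAATCTTGCACTA
TATGGCGGAGATTTTCGACGGCTGTAACGGAGCGATACGGTAACCATACCCATATGGTGGTGAGTGCTTCGTCAGCTGTA
GAGAGTCGCTCAGCATACACCGCAGTCATCGAGTTAGAGTGAACAAGATTGATTGCCGTTGGTCTTGGGGTTGGCTGCGG
GTGACCGGCCTTCCTCCTCGAGTCATGACCCGTACGGCTGTGCCTGTGGAGGGCCTGTAGTGGAGGAGCATGTACTGGCC
GAGTGTTGTAATTTAAAAGCTGTCTAGCTTGTACAATATGCGGAACGGACGATTTTAATTTGTCCAGTATGGATAATCTG
AATGGACCAAACACGTTGGACGTGCCCGCCCACGTGTCCGTATACTACCTAACATGTTGGGCGGTCCAAGAACGGAACGT
TAACATCGCGCCTCAAATTGCAAGTGAGCGGTCGCCGGGTCTAAGGGCCAGAGAAAAAGCGCATTCAGTCTCCAATACGG
GCAAGGGCTTAGGGCGGATTAGTTTCCTCTACCCCAGTATGGAGACTCGCATCCAACCATTCGGCGTAGTAGATATTCTT
AGTCTATACCGCTATATCCCAGTAACGATCACTCTCTATATGCAGCTAGTCCCTGCGTGTGCTGAACTGCCAATACTCGT
GCGTCGCGTGAAGACTCACGCTCTTGATAAGGTAAGCGCTTATCACAATGCCGACAAGTGGACGGCCCATTGCCACACCT
TTGGGGTTCGATACAATCGCTGGTATAATCTTACCTACACCGACAACTGCTGAAACTAATGAGTACTTGCATGAGGTCGG
TAGAAATGCGGACTTTCTGTGAAGAGAAATTCGGGCTTCATAGATACAGCTAAGATTGCGTTCTGGTCGACAAGCACATT
CGTAAGCCTATAAAAGAGCTCAAGATATGGTTGCCTTCTAACGATGGGGTATTGCCAGCGTCAGGTTTTTCCATAGGTAG
CGGCTGAGTCGGATGAGACAATGAGGGCCGCGTCATATAGGTAGCGCCCAGAACGCTGGGCGGGCAGCTGTGGGGATTCT
TGAAGAC
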