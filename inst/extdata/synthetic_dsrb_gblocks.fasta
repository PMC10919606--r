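>gBlock1
AGTTTGGTGACAGTTCGAACAAGGGCAACATCGTCCACACCCAGGGACTCAGCTATTCTACGCTATGGCTACGATGCGAT
AGGATGTGGACACACAATGGGCAGTGTGACAAAATAACCTGGGACTGAAAACCGAGTGGATCCCCCGAACATCCGTCGTG
TTTGTTATGAACGACTAGGAGAGTGGCCCCCCCGAGAAGTCCAGATCGATACCCCACTATAATGATGAACTTGACAGCAG
TGTGCGGCGGAATGCGCAGCGGTATCCTAGTACGGTCAAGGTAATCCCCACATTCGTAGCTAACAGCCAGCTTCACCTCC
ACAAGTATTGTGCGGTAACTGCTACACATCACGCGTTGCGCTACAAGCGGTTGGGTGCATACGTACACGC
>gBlock2
TTCAAACAGAAAAGGCACTGTCATTAGTCGGGCTGCCAGATTAATAAATTTCATCTACGCCCAATGTGGTTAATTCGAAT
GGATTGTGGACACACAATGGGCAATTATGCAGTATTACGACACCAACCACGCAGCGAGAAGTATTCTTTTTAATCATCGC
CAAACCATACCTACCGGAGGCCGCTGTGAAACAAACGCCAAAGGGTGTTTTCGAGAGTATCCTACTAGGACCAAAACTTA
TCGGGATGGAACTAAACATATGCAGCAGCCTACGGTCAAGGTAATCCCCGTGGCAAGGCAAATAAGCCTACCTAACCGAT
CTTAGCATAGTGGAAGGTGATGAATAAACGCCTACAATATAAACTGGCATTTTGCGAGACTCAAAGCCAG
>gBlock3
TTCGGTACCTACAGGTGCTTTCCAATCAAGTACCCCTCGGTGGGTCCTGTTATATGATGACGGCAGGTTTGCGCGGTTCG
CGCTTGTGGCCACACAATGGGCATGTGCCGGGATGACGATGCTGCGTCGGAGACGGTGCATTTGTATGACTCATTATCAG
GTGTTTCAGCGCTCCTGAAACGCCCACGGACGCTATCCTCGTCGAGGTTTTAGATAGATTATTACTTGTTTGAGCCACGA
CCCACGCCTGTTAAATTGCCCAGTCCGGCATACGGTCAAGGTAATCCCATGGTTAGGCCCCCTCACGGTGATCAATCTCG
TCACCCGCAAGCACGAGCCAGGATGATTCAGATGTTTCTCAGGCGGATAGCAGGAGGACCCACTGGGTTG
>gBlock4
AGGCGATAAGGATGGTAATGCCAATCAACATCGTCCACACCCAGGGTGTTCTGCTGCAAGGCTATGGCTTCGATCCAAGC
GCATCGTGGACACACAATGGGCATGGAGGCCCCATGCGTGGCTCAGCGGGGTTCCGAAGGCAAGGGGTTCTATACATAAG
CCGTACGCGGGTTGCGACGCGTTAATCCTCCTGTGGTGGCTAGAGGACCTCCCCCATACGATTACCAAGTATCGTGACGC
GTCTGCCCGAAACTGCTAGCCATAGCCGTCTACGGTCAAGGTAATCCCGGTTGAAGCATCTGCGGTAACTGCTACAGTCG
CGGGCATAATTGCGGTAACTGCTACACGAACATAATTTCTCCGTAAGTTCTCTACCTCGTGATGGGGAGA
>gBlock5
GGACCGGGGGCGCCTTCCGAGTTTGCAACATCGTCCACACCCAGGCCCTAGCGATGCAAGGCTATGGCTTCGACGGGGAG
AAGGCGTGGACACACAATGGGCAATGTCCGCCGTTTATGTGTTCTATCCCTCGTTCATATACAAGAAGCGCGGACCTTCG
GGACCCGGTTATACGGAAGCCATTAATATGTATTCTACCTCCCTTAATCACATCGCTGAAAAACCTCACCATGGGTGTCA
AAATGCACCAAATACGTGCCACTAAGAAAATACGGTCAAGGTAATCCCCAGACCTGTCGCTGCGGTAACTGCTACAGCGG
GCATCGCCTTTGCGGTAACTGCTACACCCATGACTCATATACGCTGTACTTCCTTCTCGTCATCCCTACG
>gBlock6
ATGCTTGCAGACGGTTTGAGCCACTTGGTGTGGCACTCAATCCAGCGGTGCCGGTGCAAGGCTATGGCTTCGACACCTAG
CTAACTTACACCCAAGATGGCCGAGAGCGATTAGCCCCTGATAAGGGGTCAAAAATACATGAAAGCAATCATCATGGGGG
GGGGGATATTGTCATTAAACTCAGGCCGAGTTGTTATATTTCAGTAGGGGTTGTGGCCAAAATGTAGACGGAAGTAAACA
CAAGAGGTAATACTCCGAGCAAAATCTTCGCGCGGTTACCGCCAGCCGTAGAAAACACACTGCGGTAACTGCTACAGGAG
TTCGCCTTCACCATCCCTTCTCACATCCCACTAACGGAGACAGAGACTATCATTCAATTTTCACCTCAAA
>gBlock7
ATATGTCGCGGCACGGACTAGCGAGAGAAATACAGGCTAATCAGCGCATCTCCCGGCAAAGCTATGGCTTCGACTCAATT
TTAAATAGCTCGGAAAAGTGGTGCATGCCGCCCCTGCAGGTGGAAACACCAATAATTTGTACCTGACTGTAAGTTTGGAG
CATTGCACGTTCTCTAGCGACTATCACCTATGTCTTTTTGAAAGTTTCGTGACTAGTATATCTGAACTTACAAGACAGGT
TCATTGGACGGTGCCGACAACAGTCGCAGTAGTTAAGCGCCCGCCTCCGTTAGTGATTAATGCGGTAACTGCTACAGTCG
CAGCCATTGATCCTGTCCTTAGTCAGCACGAAGTGTAGCCCTTAACGTTTGAGCTCTGATACGGTACACT
>gBlock8
TCAGAATACACGGCGCAGATTTGAACAACATCGTCCACACCCAGGATATAAGCTTGCAAGGCTATGGCTTCGAAAGTGCA
CTCTAGTGGACACACAATGGGCATATCCACCAAGGGTCCGGCACCAACCATGGATTAAATTGTAGTTATTCGTTATGCCT
GCCGTGAAAAATACCTTGGCTACTAACCCCCTACCGTACGAAGATCTAGGAGGCGCAATTCGTGTTTCCTGTGCTTTGAT
GTATTCGATCCCAAGGCATGATCCCTCTTGTACGGTCAAGGTAATCCCAGGTTGATGAGATGCGGTAACTGCTACAGGAA
GCGGAAGGTCTGCGGTAACTGCTACACCTATAGTCGGAATGACTGTCTGTAGTGTAGGAGCATTGCACTG
>gBlock9
ACTTGGACGACGTGCCCGGCCCTAGCAACATCGTCCACACCCAGGCGTATGGATTGCAAGGCTATGGCTTCGATTTCCCG
GGCTCGGAGTACGGCATCCAGGGTAGGTCGTTATGGTGGACATACAGGCTCTCTAGGCAACCATGCAATCACAGACACGG
CGCGTGATAGACGAGTAACGTAGTTATAACCAACGGTCGCCCAGGGGTTTTAAATGGTAGCTTCTGAGATGGCTGCGATT
TGTCCGAAGTCCGTAGGGAAAAGTGCTCAATTAAAGCATTTAGCACCGCAGTACCCTTTTTGCGGTAACTGCTACAGATA
TTCGAATTATTGCGGTAACTGCTACACCGTTGAGGTCAAGCATGAACATATTTTTGTCCAATTAACCGAA
>gBlock10
ACATGCATTCTAGGAAGCGCAATCACAACATCGTCCACACCCAGGCTAGTGACAGTAGTGTTAATAGCTGAACCTATAGC
TTATAGTGGACACACAATGGGCACGGCCAATGACCGCCCTAGTGATGGGTCTTCCCCCATCAGAAAACTTATTTGGTAAG
TGAGACCTGAATTTCGGGTTCCCTGAAGGGCGACCTCACTGAGTGGAACTATCGATCCCATTGCCTTTTAACAGCACAGC
TCTGCCCTCGACGTTGTCCATAGGTGTACATACGGTCAAGGTAATCCCACTTGAAGAAGTACACCGACCAGTTTAGTCTG
TGTCGTCGTATGCGGTAACTGCTACACTATGGTGCCTGCGGCCGGCGGCGATTTTTCACTAGTAGTCACA
>gBlock11
CACGGCGGATAACGTTATTTAGGCCCAACATCGTCCACACCCAGGTGCCCCTAAAGCAAGGCTATGGCTTCGAGATCGAT
CTCGGGTGGACACACAATGGGCAAACTAAGCCGGTATCGCTATGAAACAGTCAAGGATCTGGCTATACCCCCTTACCCAA
TTACTTAGAGACTCGAAGGTACAAAACACGTTAAGTCTCGCATCGGACCGGACCCTTCGAGCTCTCTTCAGAACCTGCCG
CGACTGGAGATACTACAGTCTTCGTGCTAGTACGGTCAAGGTAATCCCCGGAGGTATTCATGCGGTAACTGCTACAGCAA
CAAAGGGACTTGCGGTAACTGCTACACGATGGAAATCCAGCAAAGCGATTTAAAGTTGGGAAGTCTCAGT
>gBlock12
ACCTAATGTGTTGCCCGGACCTCACACAAGCGTGCCTATTCTACAGTTTTACATGGCAAGGCTATGGCTTCGACAAAAAA
TCCCGGTGGACACACAATGGGCATGAAGCCCGTTGAATTCTATTTGCATTCTGTATGCTAGCTAATAGGATAACAGCGGA
CGGCAACTGGACGTCATCGGGGAGCACTTTGGGGCGGTCTATGCAAACGGCGCAGCATTGGATCTATTACCGGTTATAAA
AGCCTGAGTCGTGAATTTTGCGCCCGCATTTACGGTCAAGGTAATCCCGACTACCAACCTTGCGGTAACTGCTACAGTTT
CCCCGTGTCTGGTGACAATAACGTGTGTAGGAAGTTGAATCAAAAAGTAATACCACCCAGACGATCTCAT
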