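>M13mp18_synthetic length=7249 | seeded random synthetic stand-in (seed 424242), not the authentic genome
GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCC
ATGCTTAATTGCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCT
GTTGATTTAAAAAAAATCACACTGTCCGGTGATAACCTGGCCGGATAGCCTCCCTCTTCAAAACCTGGTG
ACCCGCAGCTCTCCTGCGGCGAGTTATGGCTGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGT
GCGTCCCCTCCCCCGAGATCGCTATTGTAACTACGCGACTCTGGCTTTAACCGTTGTGTCGTATGCTGCG
CGAGAGGAAAAGATTGGGCTGTAGCGGGAGCCATAATGCTGGGCTACCTCCACACCAACGGCACAGCTAG
GACGGAACAATTTTAACACGTTCTATGAACAGGAGTTGCTGTGATCGGAGCTAAAGTCACCGTACCCTAG
AGGTCGCGACCTTGTGGCTCACCCCGCCCAACGGTGCATCTACTCGATGTCGTCGATTTTTACATGACTG
AGCGGAGCTGCGGCTGTCCGGGTGCCTCTGCTGCGCTGGTGGACACTGAAAAATCTAGTGTTCCGTCTCG
TCCTCATATATGCAAGGCCCAATGTCAGCGCAACTCGGCGTGGTAAGACTACGACTTATTAGTAACAACA
GGATTGTGAAACTTTAGGAAGTTCTTATTTCAAAGCTGGTCTGAGACGAAATAGTCCTACCTTATCAAGA
GTACTATAACGCGGTGATAAAGGGAGTTGCATTTGATGGACAGATAAGTGTGACACCGTTATTCTCAGGG
TCCTCTGTTAAAAGGCAATGCGTATTTAGTCTTAGGTATGAAGGCTTGTGAGGAGGGTCCTGGTGACATG
TCTCATAACGCAAAAACGTTGATTCCACACGACAACGCTGCAGTCCGCGCCGCGGGAACATAGGCTTGTT
TTATAATGACGGCTCGTGTAGGTTTATATCTGCCGCGTTAGGATCCTGTGCTAGGACGAGAGAGAGAACA
GAGGTCGTAGGTGCAACGCTACTTATTCTTTGGCCCACCGAGTCCCTAAGAAAAGTGAACACCTAGTATT
CATTAATTATTCAAAGCGTTGGGACACCTATAATTCAGTGACGCCTTTCGACACACATCTCATGGTGGGA
CTCGTGGTGTAAGTGGGTTCCCCCTATTTAACACTCGGGAGGAAGAGTTGGCAAATTGTGTTCCCTATGC
GGCTACTACGGAGCCACGTGTAGCACTGGGATGCTGGCGACCAATCCTGTCTATCCAGTGCATAACTCTT
CATCTCAATGATAGTAGCGATATACTAAGGAAGAAAAGGTGCGCTATGTCGTAAAGGATCCATTTAAAAA
GCCGAATTTATTCCCTAGAAAAAATAATGCGAAGTCGGTCGTAGATTCGCTTGTATTATGTTGTCGCGAC
CGAACCGACTAGATCCAGATGGACCAGCTAGGCAAACGTTGTACTGCGACATGCCATGATGCACGGGTAA
GCCCTACATATTGGTTCGCGCCTAGCTAAAAGCGAAAAACTCTTCCATAACGTCCTGCCCAAGTGTCGCC
CCATTGTTGGAGTACCATGTTGTGCTTGTGCGCCCACGAAAAGAATTGCCTGAGGAAACAGCACCTTAGT
TTGTGATTAGAGATTCCCTTCATGCGGGCTTTCATGGAGCTGTATTGATAGAAAGGGCTGTGAATCAGCT
ATCGTTAGGTCCATTCTTCCATCATATCCAAAGTTCTACGACCGGGCCGTTCCGTAACTACCCTGCGGTA
GCCAATCGTGGGGAGGCCTACATCGGCGTCTACCCCCTGCGTTGGTGATAGGCAAGAGCCCTTCATTCCG
ACCTCTCGGTACCCATAGTAAATGCTGCGGTGTTACATATAGCGGCGAGTCCGGGCGTCCCGGATCAGTG
TTAACCCGGGTGATGTACTTAAGTCTCGACTCTTCCCGGGTATCAAGAGACTAGTCGTCGAGTATGTATC
GGGCGAGGCTTTTGCCGATCCCTGGACACTAGCAATCGGGAAGCTCTTGCACGTTGGAAGAGGAAGCATC
CTAGCCTTGTATCCAAGAATCAAAGGCTCTAGAGGGTCGCGGTACGTACCGGCAACTGGCACTGTGCATC
GGCTGGGCCGGACGCTCATCATGCACCGCGTACCTCTGCTCCGGTAACTCAAGAGGGCTCGCCATTGAAA
TTAAGTTTCAAAAGTGGCTGAATGGGGACGACTAATAAAAATCCTCAGACCCGATCAAATAGGCGGTTCA
CGTTTTTTTGAGGCTATACATAGTTTAAGGAGGTCCTGGTTTGGGCCGCAGACGTCCAAAGGCTAAAGCA
CTCATGAATCATCATTTGTAGGCATACATCTAAGACTTTTATTGTATTTTTCCCCGATGACACCCTTCAG
CGACTAATGGCGCTAACCAGTTTGCATGATGTCGTACATTAGCGAATGGTGCCTTATCGCCTTGAAGACT
GAAAATACATGTGAGAATCGGATAGTACCGAGAGCCTGCCGATCACCCCGGACGTATAGGCTAAGTTCCC
TTCGCAAAACCGCCCGTCATTATCTCTAAATTAATTCGAATTCAGCCGAGTGTCTACCCACGACTATCAA
ACGTCTTTGCCCGGTCCACGTGCTGTGAAGCAGAAGTAGTATCTATTGATGGGACAAGATTTCGACATAC
AACCATCTACTGCGCGGCCTGCGCGTAAACGTATTATGCACGCACGATGCACTTGCAACTTAAATGGCTG
ACATTTAGCGGCCACTCATCGATCTCAGAGGGGCGCGGTGACGATGGAAACACTGAGAGTGTCGTATAGT
AGGATGCAACCCTTCTATCCCGACCTGAACTTTGACCAACCCGCTGTTCCATTCCATCACATCCTGCAAT
TGACATTCCGCGCTGTCACGACCAAGGCGTCGTTCTGCTGTAGTCCTGCGGTAATGTGTTGATGCGTCAG
ATCCAGAATTATAGTACAAGTATTCAGCAATGCGCGACAGGAGCTCCTTTGAGTGTACCAATCCGTCTTG
TACTTCCTCAGATCGCCGAACGCCTGATCTCCGGGCTCCATTAACTGGGGTCGCGCTTCATTATTACGTG
GTTACTTATATATTGGGAGCAGAAACCTCATACATCTACTACTGCCGTCCATTTCTACAATAGGACTGGG
GTAGCCAGTTTTTCTAGGTAAAGACAAGGTCAATGAGCTCGTACCTCTGCCAGACAGGTCGAGATGGTCG
GCACCTTTGCGATCCCGAAGCCAATATGCCGCCTCACGACAACGGATTGGCACGCGTACGGAAGGAAGCT
AGCCCGTTAATCTGCTTAGCTTGGCCCAACCGCTAACTGTTTCACGGGCCGTGACAGCTTACCAAATTGG
AAACCTCTGGAGCGCGTGTGGCCTGCACGAGCTGCAGCGATGCGGCCCTGACCGAAACGCAACCGTCCTC
AGACTATGTCCGGAGATTAAGGGTGCTGGTACCAATTCCGGTATGGCAAGCGTAAAAGGAATCGTCTGTT
AGGTCGGCGGCTGCCCTAAAAGTTATCAACTGTAGACCAGGAGTACAGTGGTTGCGATGGAAGACGCCAG
CCAACTGTCTCTTCTACTTCAGTCTAGAGATGCGAACGCACTAAATTTCCGGAAGCGACTTGTGACATCG
CCTCCACAAATCTCCTAACTGAACGGCTAGCGTCAATTTTTATGATCGTGTTAGAATTAGGGTTTGCAGG
TCCACAGGCGAAATAGTACTATTCCGATTGGTGCCTGCTGGCGCCGAAGGCCTCACGGACGTCGCAGCTT
TATCTGCGCAAAACCAGTGTAGCGTACGATCAGAAGAAACAGCGGTTATTTGTTTAGACCCAGGTCGGAC
AGCCGTCCATGCTTTACGTACGGTATTAAGCCCCAAACTCGGCCAAGAAAGGTTAGCCTGATCGGAGCAG
TTGGCACTGAGCTTTTTTCCGCGAGTATGACTCCGCCTACCTTGAGACTTGCTAGCTATACGGGCCATTA
ACCGGTCACACGGGTCTCTACCTGGAGGAAATTTAAAAGATGGACCCATCCCTAGAAACCATGTTCTGTT
CTAAGCCCTGTGACCCAGTGAAATGACGGACAATCTTCCTGACGCCGCTACCAACCCTCTGCCAATACAC
CCCGCGAACCACAATAAGTGCATAAGGGGTTTAGGCCTGCCTAAACGGGGTCGATTATCGCGAAGACGGA
GTCGGTCGGCTCAACGCCCTGCGATCACTTCAACGATCTCATGGACATAATGAGAACTCCTCTATAAGGT
TATACGCGAGCCACACCTTTCCGTCGGACTTCCTCAGGTCCAAACATACGGACAGTAAGATCCGACCACC
TACCACTCACACTTTGTGAGGATGGGCGGGAGGCGTGCAATGTGACCTCAGTGTACACAACATCCTGCAG
GACATCCAACGGGAGGGAAATCTTGACGATTATGTGGACTACCTGATATCCAAAATAAGTTCACCGATGG
GCCTCAGTGCGCTGAAGCGATAAAACGAAATCTAGACGGTCGGTTCCTGTGATCACATTCTGACCTCGAC
AACTGCCAGCATCGAGCCATACAGCCCTCGCGGAGGTGGTGGAAGCGAGAAAATTGTCAAACAGGCATCG
AGCCGAATAGGTCCACTCACAAATTATTATCGAGCGCTCGCAGTAGGACTCTCGTGCTTAGCGTCGACGT
TGAAGGAGCGTTGGCTTAGGACATCGAACCTCAAACATAACATCCTCGCCAACAGGTTGGTTAAGCAAGG
GCCGTGTGGTACGGTTTGGCAGGTCCAGTAAAGCCGTGTAGATGTGAAGGTCTATCCGAATGATCTGGAG
CACTGTAGCACCACATGGCCTTCCCTGGTGTTACTTACCCGATACTGCCACTGGCAGCACCGCTCCTATG
CTTCGAACCTGGCTCCCAGGTCCTTAAGACCGCATCTCGCGAGGTACTCTGCGATATTCCTTAAATTGCG
AGGAGATTGTTAGGCTTGACACTGACTAGAGGTTATCTGGTTACCCCCCCCCTTAACGATGTCTTGTGGG
GATTCCGCCATGGCAGATACATTCGGTGAGCCGGATTTCTCAAAAGAATGTTAGTTCAGCGTCTAATTCG
TCACTACTAGCCCACAGATTCTAATCATTCTTTAGTGACGAATCTGGTATTGCTTTCTTAAAAGAGCGTA
TACTTCCCTTGTGCCTCGGATATGCAACGCTCGTTTTTCCCTAAAACCTGATGTGAGGGGTTGGTTATCG
CCACGCACTGGGACGGGGCCAATCTTAAGGAGTGAGTAATTCGAGAGCACGGTCCCTTCTTGTCAATTTT
TCTGAGAGTGGGCCTATGGCTCTCGGACCCAGGTAACTCGTTTTTATCTACTTTGGGTTCATCCTTAGCA
GCTGTCAAGGCTAACAGCCTGTGATAAGACTATGGATACTTTACGGCGAGCTTAATCTACACGTGGCAAT
CTGAACGGACGACCGCACCATTGAACGTGCTTTGTGCTTCCTGGCAGAATCTATGCTACGACCTAGCTCC
GCTTTAAGCTTAGCGCACCATGGGCTTACTCAGCTGATGGACCAACGGTCGTTGAGCCTTGGAAGTGGAG
CGCACTGGGTTTTCGAGTTCTGGGATGAGGAGTACCATAGCGTTCTCATGCCAGGTCTAAAGTTGCTCCT
ATCATTCTACTTCGGAAGATACGTTGGTGGAATACTCTTCACGCCCTTGAAGTTGATAGTGACAGGTACG
TAGAGCGCGCTGTCTTACCCCTGTAAGACCCATGCCATTACGATATGTGCTACAACATGGTCTCTAGTGT
AGCAAAATATGATAGGAGGGTAGCCAGGCGAGGCGTGATTCGGTAATGGAAGTGGTTAGTCGCTCGTGCT
TCGATCGAAAAGGCTTGTATAGGCCGGATCCATTAAAGTGATGAAGCGCTTGATAGTCTAACTCTGTGTC
GAAGAGGTGCATGGCCCAGAGACGTCGGGAGTGGTCGAAAAAGTCTCAGTTGAGCGCACATGGGCTTTGC
GACGCGTGACCCCGATGACGTAATGCCGGTGTCTCGTCGTCTCTGCTATGAATGATTGCGATACGCGCAC
GCGCACATCAGCTTAGCCCGGTAACAAGCATTAATCCTTGAATCAGCCGGCTCCAAAGGCGAAGCGTCGG
CGAGTTGAACATGCGTACCGTATGAAGGAACATTCTATTTGCGCGAGTAGTAAAGTCTCCTATATTGGCA
GGGTACTCCAGAGCCAGCACTCTTGCAGGCTTTAGAAACCACTCTGCTCGGTCTCAACCAGCAAAACGGG
TGCCACAGTCGCGTAAGTGTTTACTATGGGTCCATCCAAGGTCAATCCCCTAATGTATCGGTAAGAAGGA
CGGGGAATGACCACTGACCTTTCAATGCATGTCTTGCACGACGCGCATTTTGTACGTTTATCTTCGCATA
AGAAGTGCAGCCACAGTAAAATTAATCTGCGTGTTCCTCCAAGTCTCGGCGCACTCCATGCCTTGGTCAG
TCATCGAGCGCATCCTCCTATTGTGGTGCCATGTACCCAGAGTCCCAGAAACTATTCCTGGGGTTACATA
AGCTTCCCGCTTAGGTAAGTCTGATTAGGGCACGATTCTGCCCTACTATCAGAAATCCTGACCATGCTGC
TTCATGCAGTTATCCCGATAGCAGTTAGCACGGCTGTCGACATGGTTTCAGAGCCGCTACTTGGCGTACC
AACGTCGAAATACTCCCGGTATTTAGGGTCACAGGAGGAAGAGAACTTACCGGAGCTTGGTATATGAACT
ACTGGGTCCATCGTTACGAGGAGCTCCGATTACACAGCACCGCTGTGCCCATTGGTGTATACTGCCAAAC
CACATGCGCCGATCAAGTTTAGCGTCAAAAATGGAGACCACCGGGGTGGACTGCTATACCGCTTGTTAAT
CCGGCGACAGATAGCCGAAGAAATTACCAGTTATCGCTTGGCTCATCTCGTGGTGTTGATGGAGCTAGAA
ATTTCGAATGTAACATACATTCGTCGCGTGTGGGAACTCAAGGTCTTTAAAGCGAGTACTAGGAAACATC
ACCCCGTTAATGGGGGTAGACCCCTTACCGAAGGAAGGTTAAATACACTGTACAAAGAGTGAATGAAAAT
AGGCCGATCGATTTACCCACGACATCGGGTTGGAGTGGT
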