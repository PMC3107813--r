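>Proteinase-1
CTGCTGACCAGGCTACTGTTTGTATGCACAATCTTGACCTTCTCGACAATTCCACTGGTG
CTCCACAAGGGGATCTCACCGATCCAAGAGAAGATGGGTAGG
>Proteinase-2
ATGATCCGGACGAGGTTCCTAGTTCGAAGAGAGGGCCTTCTCGATGTGGTCTCTCCCGGT
GAACTCTTCTCCGGAGAACACGGGGTAATCACCCCCGGGACTGAACGATATAGACTCATG
CCATGTTCCATGTCCTCTATTTGAT
>Proteinase-3
GTGATTCTTCGTCTTTCCGAGCCCCGTATCGTCGCACCCATTAGCCGCTTCGGTGAGTGG
ACCTTGTGTCGCAGACATCTTCAAGACAAGCGATTGGTTCAGATGGTGGAATTGGAATGA
ATATTCGCGTATATTCACCAGTGTCTTTTAAT
>Proteinase-4
TTGATGTTTTTGTTCCCGTCTCTATATCTTTATTCAGAGTCTGAACCAGTGACACTTAGA
TTGTTATCATATGATTTAAACCATGATAGGTCACCATCTGTAAATTCCTCATGGTTCATG
ATCCCGTGCTTGGCACATATCATTATCAGAAGGATGGCCTTCATCGACAGCTCCACTCTC
TGGTGGTCTCTGTCACTCACCGGCGTGCCCGGGGTCGCGTATTCCACCGCCGTGTCTCTG
TTCAAGACGGCGAGTTGGCCTCTGGGGATATCGGCCGCCGTGACGGTCAGGGAGTTGATG
AGAGAACTGGTCTCCATGTCAGTGTTTAGTCTCTGGAAGATTTCCTCAGCGGACATCTCG
GGTCCCGCTGCTAATGCGAGCCTCAGGGTTTCACGGGTAATCGATAGATGCACCCGCTTG
TGGCTATGCCGGGCGGCCGGCCTCTTTCCTCGTACACGCGGGGTTGGTTTGGGTTCGGCC
ACGTGCGCGCCCCGGCGTTCCAGTAACGTAACCGGACGCCTCGAGGGGACCCGCGCGGGC
TCGGGATCGGCCCCGATACCACCGGCCGGGACACCGATCAGTTCCAGTGGCCCGCCCGCA
GACGGTGGGTCTTCGTCCTCGCTCTCTTCGCTCTCCTCCTCGCTCTCCTCCTCCTCGCCT
CCACTCTCCGTCTCGCCCCCTTGTCTATCCTCCTCGTCCTCCTCTCGGCACACTCCATCT
CCGCGGGTGCCGTTCGAGTCCGGCACCGGATCGACACTCTCATCGTCACCCGATTCCTCA
CTGCTGAGCTCACGACCACCGGCGTACGATCCGTGGTAGT
>Proteinase-5
TTGATGACGTCCCAGTTCGCCAGGTCGGGTCTCACCATCGAGAGAAACGACATCGCAGAA
TCCAGCTGTCTGGTCGCGACCATCGACTCCATGGCCTCGGCGAGACTCGTTCCTTGAT
>Proteinase-6
ATGCTGACACACACCACCCCGAACAAGGCTGTACGTATCAGGTGCATCAAACCCAGGATA
CTCGCGGGGGGTGTTCCGGGTGTAGCTCTCACTACATACCGAAATTTTCCGAGGTCGGAG
AGGTCGCTGCAGCTGTTGTGCTTGGTGCCGGATTGTGTGGCCCCCTTACCGGTACTGTTG
ACAGTCAGCGTTCCGAACTCGGTGAATTCGGTACTGTTGTACACAGACCACAGGCAGTTG
ACAGGGAAGACCTTCCCGGGTTCTCTCTTTTCGGGTATCTCTAGGGATTCAATCCCAATC
TTGTTCAACCACTCGATGAAGGTGGTGGGTCCCTGTTGGTTGTAGA
>Proteinase-7
CTGTGCGTCAGTTGCTGTAACTTGACATCCGGGTTATCGGTTGGTTTCACCGATAGATCG
ACCGTGAACGGACCCGGGGGTAAATCGGCGGGCGCGACCTGCAGGGCCGCTCCGCAAGCG
GTCGTCCCCATGAATACGTTCGAGCATATCACCGCCACATGTGCGTCCTCGAGGTAGT
>Proteinase-8
ATGTAGATGACCATGTCCAACTTGAGAGGTCCAATGTCTACCCCCCGTGGGTCGTGGTAC
AGAATGTGTGTGTTGTACATGTTCGTTATGAAGTTGATTCCATTGTCTCGGAACGCGACG
GCGAGCGAGATGAGTTGTTTCAGGATCACGGCCCCCAGGAGGGTTCCATCGTCCGTCTCG
CCATCGAAGTTCAGCTCGGTGATGGACCTCTTGGCGGGGGTCACGTAGATCATATACCTT
TTCGTGCCATGGGCGCCCAGGGTGTAGTGGAACACCGGTACCACATATGGGATAGATTTT
TGGATCGCCTGGATCCCCTCCATCAAAGACTGTATCGCCTCGAAATCAATGGTCGGTTTC
AGCTCGAGGTAGACGATGTCATACGTAGGGGAGAATTCGGGGGGCCTGTATACCCTGATC
TCCTTCACGCCGTACTCTTTGGTGGCCACGACCGGGTACACGGAGACGAGGTCCCGGGGG
GTGAGGGTTATCAGTTTCTTCGCGGTGTGATCATCGCCCATGTCTGCGCGCGCAAGCCAT
GGCATGTATAGC
>Proteinase-9
CTGTGAACAAATATATCTTCGAAGTTTGCCGCGAGGGTACCGACGAGGTCCCGCACGCGA
TCTACCAAGACGGTTTCCAGGACGTGTCTCACGACTGGAAGGGCCGGGCCCGGCCATATC
ACCACGATCGAACCCGGGTCGAGCGCGCACTCGATAGA
>Proteinase-10
ATGCGTACACCGCATACGCCTTCAGCACTGCACTGTCACGGCTCAGGTCCCATTTACGAC
GTGCGGGGTAAGGCCTGTCTCCCTTCAGAAATTGCGTGAGCTCGTAGTATTCGCTCAGCA
CCCTCTGTCCCAGGAACTGGCGTATCCGAGGACAACCACCCCTCGAATGGTACACGTGTT
CGTCCAGGAAATCATCGACGAGCGTGAAGCGGATGACCTTGACACCGCAGTCTGGACACA
CGTGACGATCGCTCTTCACATCGTCCGGGATCAAACCTCCCTTGGGTCCGAAGTACAGTC
TCGTCATGAACACGAGGTTGTCATCCTGCAAGGTACCGTGGGCGACTATTGTATCGTAAT
CCAAGGTAACATCGCAAAACCACACACCTCCGTCCGCACGCCATCCGCTTGGCTTGAGCA
TTCCCCTGGGTGCCGCGGACCATCTGAACCCCCTGTCCGTGGGGTTGCTGACCCGCTCAC
CGTCTGTCACCAGGGAACCGCATTCGAAATCCATCGCCTCAGTAGTGGATTGTCAGAGAT
CGTTCTATGGGTATCTGGTCAGTGTGAATTATTGGAATGGGCGCTCGCAGTATTCTTCAA
TCGTTCTTTTTCGGGCACCATGAGACTCTCGGGATCGAGGAAGCCGCCGGCGGTCCACCG
GATGCGACACGTGAGATCCGATAACCTATAAA
>Trypsine-1
CTGACAGCCACGGAATCATCGGGGGTGTACACAACTTCCGAATCCACGGAGTCCATCACC
GCGGTGGCGATCCCGACCATCGCACGGAGTTCGGCCTCGGTCCCGATCTTCTCAAGGAAA
AAACCAAGGTGTTCCGGGTATACCTTTAGAATTCCCTTCGTTTCCGGGTTGATGAACGCG
CAGATCATCTTGTTCTCGGGTCCTTGTATGATAGGCAGGAACGCGGCCGTCTCGTGCAAG
CTATCGAAACGATCCATATCATGGGCACCGCCGATGAGATCCATCCCGATGTTCTTGCGG
AGTGCATCCATTTCGCTCACAAGAAGATAAA
>Trypsine-2
GTAGAGGAGGGCCCGAACCGTCTTCCTAAATGTGAGACCGGGGTGGTCTCGGAAGGACGA
CGCGTCAGTCGGGCAACCCGCCATCGTACCGGCCAAGAGGGACTTGACACAGGTGCGGAT
CATTCCCACCTTGTATCCGATCTGGATCGCCCCCTGTGTGACCTGGTTGGTCAGGCTCAT
GATCTGTTGGTACCACTGCTGGTACGCCATCACTTCCCCGAGGCGCTCGTTGGTCGTCGT
ACCCAGCTCCTTCAGGCCAGTAGCTAAACGCTTGAAGTTTGTATCCATGGCCAGCATCTG
GAGGTTTATCTGGTTTTGTAGGTCGTCCACCCTCCCGTTCACTGCCCTGATGTTGCGGTC
TAACTTGGCCGATATCAGGGCGATACTGTCTCCCAGTTCCGTGATCACATCCGCGGTCTT
GTCCAATTGTGCCTGTAAACCGTCTATTTTGGAGGCTGCCAATGTGGCGACCGCCAGTGC
TGCCGTCGACGCGACGAGTGCCGCGCTGGACATGGTTATCGCGGCCACCGATAACCCGAA
TTTATCGCTCGTGGGCACCGATCCGCCCGAGGCGGGCGCGAACATCTTAACCTTTTCGTG
TTCGAGGTCCAGGTCAACGAGGCTATTTTTCAATAGTTCGTTACTCCGCTGGAAGTCCAG
GAGTATCGCCGCCGTCTGAT
>Trypsine-3
CTGTGAAGCCGGCCGTGAGGGACAAGCGCAACGAACATGTGCCTACCCCAGCGCTGGTTT
ACTTCAAGCATCACAAGGCCGAGCTGGCCAAGGCGCTGGTTGAG
>Trypsine-4
CTGCGTAAGACGGAGGAGACCGTGCTCGCGGACGAGCGGTTCCGGGGCCTGCTCGGGCCG
GAGATGGTGGCACGGCTATTGAA
>Trypsine-5
TTGGGTATCAGCTTCCGTCCGCCCCCGGAGCCGCACTCGGGACACTCCCGGGGGGTGCAG
AAGAAACAGAACACGTGTTTACACGATGCCCGGTTGGAGGGAAACACGGCCTCCCCCTGG
CAGAAACAACACGGAAAGACTGGAGACATGAT
>Trypsine-6
CTGGAAAGGCTGAAAAGTCCACCGGGACTGCGAAAGTGAC
>Trypsine-7
CTGGAAACAGAACTTCTCGAGGCCATCCGAGACGGTGTCGCGGGTGAAGAGTTTCGCGTG
GCAGCCCCTCCGCGCGGGAATGACCACGACGCTGCACTCCAGTATCACCTCGTTGAGGCC
CACATCGAGGGTTCCGAGGCTCAGTGCACATGGTATGTCCGCTTCCGTGAACGTCTCCAC
GCATCTCTTGCCGGTGTCCTCGGACTCATCTATCCCTCCTATCATGTTCAGGTAGACTCG
GTCTTCCATGTGGACATGCCAGTAACCGAGGACCTTGCCCATGGGGATCTGGTGCGAGTA
CTTGAGCGTGCCCGGAGCGACCTGTACCATTGTTTGGTGGGCCTCGATCGGCTGCTGGTA
CTTGCGCATGTGCGCGGGGATGGAGGGGTCGTCGACCGGGTCGCCCGGGGAGAAGATGCA
ACATGTCCCAACGACAAAGGTTCCGAACCCCGTGAGTGGAACCTCGTATAGC
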