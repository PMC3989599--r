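>chrS1
ATTCACGAATGCTTCCGCATGAAATGAGGGTTCGTCCCCGTTGAAAAACTTGTAAAATTCCCTTATTCCC
GGCGGAGATGTGGGAGAAGAAACCATGGTCAAGATCGTTCTGTGGGCTATGACTGTCAATATTTATACGG
TACCTGGGGGTACGGCACGCTGGAGGGAATAGTAGTTCTGACGACAAGGCACCCCACCGGATCGCCGATC
CTGTAAAACAAAGAGCTTCTATCACCCTCAAGGCGGGGGTGTAGGCCAGAAACATACTGGCTTATATTTT
ATTTTGCCGTCCGCCCCCTCTCACCGGTCCCCCTTTTGGGATCTGAGAGTCTGAATACAACCCGAAGCGC
GTTTTCGGGTCCCGCGGCCCGCGATTGCGCCCTACAGCATGGGTAACTAGTGTTGCCAATAGACCGCGCG
CGGGGCGGTATAATTGTAGGATCCTCAGGCGGGGTTGGTCTTAGCTGTACGCATGTGCGACAACCACCTA
AGGACATCCTGGAACATGGGATGGCGGTAAACAGCTTTGTAATTGCGTATTTCTCGCTCACACCAGCGTC
CTACACTCACATGTGGCGAAGCTATCGCATTCTCAGCAGCGTGGCTCCTTTTTCCAACCCGACAACCTCG
CACCTATAACAGGCTCATGATGGTGTCTTGGCTACGTACTATGCTTAGTACTCTTTAAGAACGTAGGCGT
CTATTTTTAGATTCTGTCCTAATATGAGTGCTACACGGTAACTTAAAAAGTGGAAGTTATGGCCCTTCCG
ATATTTACCATGCACGTGCCGCCGACTGGCGAGGTTTCGGTGGAGTGTAATGTTGGGGCCTCGTACTCCC
GAATCCCGATTGCGGTGACATGTTGACGCAGGGGTGTAGTGCACCTCTTATTAAGAAGATACATAGGCCG
GTCAAGGGAAACAGCAGCGAAACGCCTACCTTCAACCGTCGCGTCTTACCGACTGGATAGGGGAAAGCGA
CAGTGCTCACGGGTTCGTATCAGAGCACATAGTTCTCCCGATTCTGGCTCGCACGTACTGTTTGCTTAGA
AGACGGTCCGAACTGGAAGTGGCTCGAACGAACGTAGACGTGGCCGACGAGGTCCGGGTTGCTAGAGAAC
GTGGTTTTTACTCCTCAACGCCAGGACGCATGAGATTGTGTAAAACAAGTCAATAGACCCTGTCGCTCCG
ACACCGGCGTCTATACTAATCACCCCCTCCTGGAATCGATTTGCTCTGTACGTACACTTTGATGATCTCT
TCTAAAGGTGCGCGTAATGGGATTGTATGTGGGCGTGACGAGGACAGGTTTGGACCCTCAACCGTGGCGA
GGTGCGTCCATTTGTCACGTGTGTTCGGAGATTCTTTGTTGAAGTTAAACCGGCGATTTAGCCGCTAATG
TTGATCGGTGGCTAAGACGTGTTTCATACTCCGGCTGAGATAAGAGCAGTCGCTGCATCGACAACACTTG
ACGCCCTACAAATTGGCGTCAGCAGGTACATCCTGTCCCTAATGCGTTGTTTATCACGGTTGGGACTAAG
CAGGTTCTCTTAGTTCACTATTGCCTATAGAAAATCCCAGCGCTATGCGTCGTACAGACCAACAGATGAG
CAATGGGGCCTACCACCACTCCGATTGCAAATTAGGAGGTGGAACAAACCCGTTCAATCACTCAGAAGAC
ATACGGTAGGATGGGTAGAGAGCCTGGCTCGTCCTCATCACCCCTAGCTTAAGTCATGGGGCAGGCGAAG
AAGCGGGCCGTACTCAGTTAAACCGGTATTTAGTACACTTAGTCTCCAGCCTACCCTCTCTTTTGTGTGT
GGCGCGAAGGGCAGTCAAATACACCTCATATGAACGCTAGGATGGGTGACCACCAGCAAGGTACGGCTTG
TAGTGTCCGCTTCATGTATATTACTAGCGTGAGAGCCGCCTAGAATCAGATACGCGATCGCATTGACGGA
TCATCGCTCTGGCCAAACACACCGCCTCGTCGGAGGAGTGTGTAAGACACGCGCATCAGTAGGGGAGCCT
AGGTTTTATGTTACACCTCTATCAAAGGACTATGCGCTCCCACTGTCGCATATGAGCCGAATAGCGTCGC
TCACATACTTTATCAGCCTTTGTGCTGTGTCCAAGCTGAATAATCCCGATATGAATGCTTCATCCAAACC
TATTCGGCATAAAGTCAACAACAAAGCCCAGGTTTCCGGCAGAAAGGACAAAAGTTTATCCACGGGGGGG
GGCACCGTACAAGTCCAACGAGAGTGGGTAGTCTGGTGGCAATTTCCAAAATTCGATTACGAATGTGGCT
GGAGGCCTTCCTATCAAGCAAGCATCGGAACCTATGAAACGAATGATCGTTGCGTCCGCTTAACCCAGCC
TACTCCCCCTCTTATAGAACAGGGCCAACATAGTTGTGTTGTGAGCGTCTCGACATTTCGGCCACACTGC
AGGAGGAAATCCTGGGCAACCCGTATATGGTCTCAGTTTGCTTGGGCACAGCCGTCCTGGTATAGCAGTG
CGTCTCCCTGCCCAGCGTTGGACGATGAACCACCCCATGCGCCAAGAGTTTACCACCCGTCGAGAGGGAC
TAGCTCCTGAAGGTAGAGGACGGACAAGCACATTCGCGTTATGCAAACGCACGGCGCGGTTTCTCCTTGA
CAAACTACCGTTTCGCGAGTAAAATACAATATTTCTAATGTCCCTGTCTGTAACCGTCAATGCGTTGATC
TGCCTGATGTCCTTTTAAGTCTGTTGATAACGCTCTGTGAGCAACCACCTTACATCTAGTACCCAAGTAG
ATTGTACTCGTAGCGGGGCATGGTGTGGTGAAAGACGGACGGCTACGTAACTGTAATCATACATACAAGG
ATTAGGGTACCGATGGTCAACAATATAATATAGGTACTAAGGGCACACAACATCTGCTCCGAGCAACTCG
GTCTTTACCCACACTCTCTCGGTTACGGACTGCGTCAATGCGTAAAGAGCCGAATAATCTGTAAACCAGC
GTTCGGACGGGGGTGGCAGGAGTCGGCTTGCTGCTACGCCATAAAGGTATCGTCATCCAGCCTGTCTTAG
TGAACGCGGAGAGGAGTGCGTCGACCGGGTCCACGTAAGACAGGCCTGGAGGTTCAGGCTCATTTCGGGA
TTGTACCGGAGAAAGTATGCGGTTAGGCCTCAAACGGGAATAAACTAGTCCCGGATAGCGTAGCGCAGCA
GTTGTATGGTAGCCATTGCCTGCTTCGAAGCGACCGTTCTGAGATACAGAGGGAAAATCATGGTTAGTCC
CATCCGAAAGTTAATGCGGAAAACCAATACTTGGATGTTATGGTTTAACCCATCCACGGTTCCTACGAGT
TACCCGTCTTAGGGTGCGACTCCCTTATAGAATTGATGAACAGGGTATGTGCTCTTAGATCGGGGGGTAT
GGCACTGACTTTATACGAGTGGCTGTAGGCCCTACTCCCCCGCTCGTTTGACCCAGTTGCGAGAGTAGGA
GCCTTCTGAAGTGAGCAGTGGTGTAATGGGTTGCTCATAGCACCCGCCGCAACCATTGCCCTGAGGGGTT
GACTCAAGTGCACTGATTGCGTAGTTCAATGCGCGTGGAGGTCGGCTAGATATACCAAAACCCGCAGGAC
AACTCCGCGCGTATATAGCGCTAACGTCGGCAGGTAACCCCGGCCCGGTCATCTTGGCGAGACGCCAAGA
GAATGCCTACTGAGTGAGATGAGATGTCAGCAACTATATACCAATTTTTGGCCAGCTAATAGCCTATGTT
ATTCGGATACGGGCTGTCTCAACCGCTATTGTATGATACGGAGCCAAATTATTCTTGGAATAGCGAACCA
GAGATCCGTACTAGCCTTGAAGAGAATGGGTACGTAGAGCTCCGCCACATAGCCCTTTACAAATGGCTTC
GGCTCACATGTCTTCTCGGTCGTTTTCCACATGTACTCACAGCGCTCTGTATTGTATCTTATACAGACAA
AATATTTGTACAGTCATAGGAAAGCGGCGTACTGCTGCCAAATGGACGAGGCCTATCATTTCACCGATCA
ATAGCAGGGAGGGGTAGTGCGAGATACAAGGCTTAACCTCGTTTAAACGGGCCAACCAAATGATTATAGT
GATAGAGGCCGTTTGGTGAGAGGGAGGAGTGTGGTGACCTACCCCGGCACTATAAAATTTACGTCTTCAT
AACCTGAAATAGACTCAGGTCAGTACATCACGTGGGGAATTGGTAGCTTCTCAATGTGTAAGCTGGCTTG
GTGCCTACGAGCATTTCGAGAACGTTCTAGGCGAAACACTGCTTAGCCCAGCAGCTATTGGGACTCTGCT
TGGCACTTCCAGCTCATTACACAGAACGGGGAGTATAGCGGAAGCGCGGGAGCCTCGCGCTTGTGGGGAA
CCACCACGCCGAATAGGGGACTGGCCAAAATTGGGATGGGGAAGCAATCGCAGGGACTACTAACTCTCAT
ATACTTACGGCATGATGGGTGTGGCTGGGATAACTGGAAACCTACGCCGCCTATGGCTCAGCTGAACGGT
TTAAATCATCAATATTCAGTATCTCAGGCGCGTCTATAACGCGTGGATAACAATCCAGCTTTGCCTAACG
ACTCACGTCCCCTCAGGCCTCCTCTGAGTGCAAATATTCAGCTCACTAAGAAATATCCTTTTATCAGAAG
CACGGTATCAGTAAGTATCCAAAACCAAACAACGTCGAAGGCGGAGCCCGGTGCAAATTCTCCGGCACGA
CA
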