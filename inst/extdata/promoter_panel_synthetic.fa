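>chicken
GGGGTGTGCCTTTTTAAGCGCCTGTATCGCCGTACTATCTGCCCTACTGAAAGATACTTT
ATATCTGCGCTTCCTTAAAGAGGCGGGCCGAATCCCATACGCGACGTACCACTCGTTAGG
AATAAAATGCCCCGCCCGGGGGGCTAGATGGAGTCTTTGATTTAGAGTAGGCTTCAACCT
CCACACAGAAACCAATGGCA
>duck
TCTCAACCAGCATCGCGTAGATTGCCGGGCCACCCGAATGTCACCATACCGCTTTGGCAA
AGTAGTTCTATGCGCATAATTGGGAGGATTGCAATTAATCGTGACCACTCGTTGCTAGTA
AATAAAATCCGTGCCTCAGTAAGCTCCTTACATGCCTAGCTTTCGCAGACTCGGGTGACA
GTGGGTGATTGGCATAAACA
>zebra_finch
ACAAATCGGCGTGATTCTGGAAGTAGATGATCGTGGCCCAATCTCTGATCCCCGTATCTT
AGGATCGGCAGTATCACCGAACTCGGGTCCCAAACTATCTGTCTCATGTCATCTTTGGAG
AATAAAATACATAGGACGGAAACTTCTCTTTTAGTGATGCCGCGTATATCACAGATCTGC
TGAATTTATTAGTCGTAATC
>falcon
GTCAAATTGCCCAGCGGGATGAGTATGTGCTTTAGCGATATAGGAGGATGGAGGTTAAGT
AACGTTCCATGAACGTAGACACGCGAAGACAACAGATCACGTCCAAAGAACCCACGCACC
AATAAAACGCTCCCTGCTGCACCTGTACAATGACCGACGCCCTTTAAAACGGAGATGATT
TTAGGATGTTAGGTATTGTG
>ostrich
CACTTACAACTGTCTGATGGCTAAGATCTCCTGCTGTACCGTCGTTTGATACGCCTAAGT
GCCTCCACTTACGTTCCTTATAGTCGGAGGCTCCATACACTGCACGGATTCTAACAAGGC
AATAAAACGATACCCAGGTGAGCGGTAGTGCACTTGCCAGTCGGCTGGTTACTATAACGA
TAAACTCGGTGGTCTGAAGA
>tinamou
TATGTTACGAAGTCGGAGGATGCTACCGGCTTTCCGGGTAGCTTCGGTGCAATGGTTGGG
CGGGTCTTAGAATACTGGCCGACTAAGTGGAAGTACCCGGAACGCAACGACCCGTCGGCG
AATAAAAATGGTGTACCCGTACACGGCCGGTAGGCCACTGGGGTCGTGACGCCGGGGCTA
AAAAGTTAGGAGCCAACTGC
>pigeon
GGAAGGGTTGGTGCGAGGATTACCGAGACAAACGGATTGTCGAATTTGGAGCGAATAAGA
TCCAGCGTGTAGACCCACATGTTATTATTAGTGTAGATCGATAAGTCGCTCGGGGTAGGA
AATAAAATGCGCCCAGTAGACTCTTCGATCTCTGCCTAACGGACAGGGGCGGAAGACGCG
GGGACCGTCAAAAGGCAGTT
>egret
CGTCTTTAGCGTCGGGGCAATGCGTTTGGGAGGACGGGTATGAGAAACGTGTTTGCATCC
TAATATAAGTCAACGGCGGTTGAATGAACCTCGTAATTGATCTCTCTTAACGCTTCTGAT
AATAAAATCCTTTTATGGCAAACAGTGCGCCCGACTATCTCTTCTGGACGAAGTGCTTAG
TTAAATAGGCAACCCTTGTG
>mesite
TCGCCGTCACCGTCATAATATAGCCAGGTGAGGGCCGCCACATAATATGCTTTCGCCTAC
CGTAACTGGATCGGACTTAGGGGGGGGGGCAGCCACCCGGTGTGGCACCTAGAAACTTTA
AATAAAATCGCCTGTTAGGCAGCCGCACTATAGTGGCCGCAATGATCGTCTGGGTTTGTG
GGCTCCAGTTCAATAATCAG
>canary
CCTTTTACCATAGGCAGAACGGAGCCCGTAGCATCAGCCGATCTGTCCAGATTGGGCCCA
CGTTCTCCTCAGTATAATCCTCGGCTTGCCAGATAAGGGAGTGAGTCCTACTTTAGGTGT
AATAAAACGCCACACAATTTGTGCGACTGTACTTGGTGGACATACACAGAAGCAGCATAC
CCCCCCCATATTACGATTAC
>emperor_penguin
GTACAAAGTAACCGATAATACAGGGGATACAGGGGGCTACCCCGGAGAAAGACAGAATAT
GATTCAGAGAGGGCAAGGGCCTAGCATCCAGTCTGGTTTGATTACCGTGGCGCGGAAATA
AATAAAAGCTCTCCGCGAAGGTATTGGACTACAGGGGGGGCCAAGAAACTGCGTAATACT
CTCCTCAAGAACCTAGTGAC
>adelie_penguin
GAACACAGGTTTGGGACGGATAATGACGGGCGCCCTCGCTATACCGTGAAGGCGATGCGT
TAAGGTACGGCATGAAATCATCGAATATAAGATTGACCTTGGCCAACACCTTCTGGACAA
AATAAAATCCACCGTTTGTCCTTCTTGATTGAGCGGATCAAAGACGCGCACACCGGCTAC
GCCCCCTCCGAATTGCTTCA
>loon
CCATCGCTCACCCGCACGCCAGCAACGCCCACATTCTCGTCGACTGGGCTAGTCAACAGC
AATTACATCAAGTACTTAGTACTAACGTTCGAAGGGTGACAGAGCATCAGCAAAGTGGTT
TATAAACTCGCAAGGGTAGCAGCATGTACGATACACAACTTGGTCGCGCGTAAAAGGCGC
ACATGACTTGAAAAGCCTGT
>lizard
AGTGACGGGTCAAAGTGACCGGCGAATACCGGTTCGACGGTACACGCTACATTCGACCGC
AAGCATATTGTTTGCGCGCGCTCAGCCGACTTATAGTCACCCGTCTCCAGGTAAAACAAA
TATAAATGGTCTAGAGACAAAAGACGTGTCACCGTGTACTATGATAGGACGTGGCTCATT
GCTCACACGTACCCAAGCAC
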