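>capA
ATGGTTCGACTTTTGGCGAAGCCGAGCATTAACGTTTCCGGGTATTACCACAACGGGGCA
AGCCCAAGGCGTCGTCCTACTGCAACTCCAAGAGTTACATGAAAAGGAGAACCACACGCT
GATACCCCAGCTCATTACCGTAGCGGCAAGATGGTTAATCAAGACGGAAACCTAGGTACT
TTGATATGCCGTGTCAGCAGAATCCGACGGCACTTCTTGGATGGCTCTCGGCAGACGTCG
TCCCGAACGGCGACGGACGATAATTTACGTCTTTCCCCGACTTTAGACCGCGTTAGCTGA
>capB
ATGCAACGGTCGCGCTATTTTCCGGCAGTCGCACAAGTACTTTACCATGCCGCAATTGCC
ATAAGAGGGGTAGAACCCATTAACTTAGTGGATCCAAGCCCCGAAACTTGGCGAAATCCC
GCCGACGTCAACACGGGAGATAGGTTGAAAAAGTGTGATAATAGAAAGATTAGAAAACTC
GGAAACGTTTAATACCCCCCGACGTGTTAGAGCGCCACGCAAACATTGCATCGGGCGTTA
CCCTTGCTTAACTCATGAATACAACACTAGCGGGCCTAGACTGTGGAATTCGCACACTGA
>capC
ATGGCGAAATCTATCGAACGCCCAACAGCATCCTATGCAGTATTTTACCGAACAAGCTGA
CCGGTGAGACTCGACTACATTTTCCACTTATCATGAAGCCAACCAACGTTGCTCCACAGT
TGAGGTAATCATCCGTCCGACGGGACTTAAATGCTATGCTATAACTTCGCGGGCTGGGCC
GAAGTCGTCGGCGGTACGAGCTAGTCTAAAGGCACGAGAGTTAACACCATGACACAAGGC
AGTACAACATTAATGTCCAGGAGTTGGCAACGACGTGGCAGAGAGCTGTAAGTCACTTGA
>capD
ATGGCCCTTCCCATCCGAAACGGGAGTCTTGGTAGTCGATTTTTTGGGAAGAATGCTCCC
AATGGGGCCCTGCATTTCTAAGTGAATCATGGGCAACGAATGCACTTTAAGTTAGCGCTA
GGGTGTTGAGAATTGCGTGGTTTCAATAGACACCATAACGCCAGTGATATCTGCAGGGGT
GTCTTTGAAACAGTGAACTCTAGCGGACGCCTTTTTACTAACCCTCCCCTACGACAGTCG
CTCAAGTGCTATGAAAGAGCCGAACCCGTCTGTCCGAAGAAATTGAATGTCCCCCTTTGA
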