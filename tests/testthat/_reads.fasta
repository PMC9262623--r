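>sim00001_r
CGGTACGGCATTGAAAACTACGCCGCCTCTACGCTACTAATTGGAACCAACACGGAACGAATGGTCAGGGATGGAACTCCCGGGCGGATAGATAATCATTGGCCCTATCCCCTCATGGCCGATTTTCCCACCATTTTCATGTCGCCTTTAAACCTCCTTTTTATAGCGATGAACGTGGGTTCCGAGCCTTACTCATATAGCCGCTTACCAGACGTGATTCTGATCGGCCATCGCCCTGAACGTACCAAAAGGAGCCAATGCGCCGCCTACTACGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAG
>sim00002_r
CCAAAGCTCGGAATAGAATTCATTTTAACCGTGATCCATAGGTATGAATACTCAGCGATTCCACGCGTTTACTATCCGCTGGTAGAGTTACAACATAGACCACAGCCCCCACCGGTACCCATATACAACGTCGCAGCGGCGTACGCTACAGGATTGCGCCGAAAGACCGTAGATCAAGCGGTTCCGTCCGTTCGCATAAGAAAGGCGCGCTTCAAATATGGTTGGTCCATGTCTCTAAGAGTGTTTAGCTACGCCCTTTGCGCCAGTTCCTATTCTGCTGCGAGGCGATACGGCTACACCTGGGGAATCGGTATTTACCAGATGGGAGCCAATGGGGCCACAGAGACTCGCCGGCGTGA
>sim00003_r
GCCCCATCTGTAAGTGAGAGTCACAATGGCAATAAGAGACCACGGCTCGACGAACCGACTCCTGAAATCCCCGTTTATGGCCACAGGGGCGGAGCTTCGATCGAGAAATTTCTCCTATCTTATGAGCCTCGAAGGAGAAGAGGTACCGGGGGCATCCGCGCGACTCCCGTACTAGTGTCCGGTGTGAGGAACCCTGCCGAAGCCGCAATGACAATAACTTCCCAAAAAATGTCCCATCTGACAAGACAGCTTCGAAGCTGCGCCGTGAGCTACATGTACGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAG
>sim00004_r
TTTCTAGCTGCCTGGATTCCAGAGACAGGAAGAAATCATCTGTCAGCCCGGATATCTCAACATGCAGGAAGCTGGATTAAAAGATATCAGCGAGCGAGCTGGCCGATTCACAATAGACAACGCGAAGGGGCCATAGGGCACGTTCACTCCGTGAGCTACCGTGCAGAGTCACTACTTGACGCGTACGGCCGCAACTTCACGACACGGGTAATGCGGCCTAATGGTGACCGTAAAGATCACCATTGGGGAACCGGGCTATGCGCCAGCAGCTCAAACACCGAGGCCTACTTCGGAGGCGGTCATGACAGAGCTAACCTGACCAAACAGACAGAGACTCGCCGGCGTGA
>sim00005_r
CGGTACGGCATTGAAAACTACGCCGCCTCTACGCTACTAATTGGAACCAACACGGAACGAATGGTCAGGGATGGAACTCCCGGGCGGATAGATAATCATTGGCCCTATCCCCTCATGGCCGATTTTCCCACCATTTTCATGTCGCCTTTAAACCTCCTTTTTATAGCGATGAACGTGGGTTCCGAGCCTTACTCATATAGCCGCTTACCAGACGTGATTCTGATCGGCCATCGCCCTGAACGTACCAAAAGGAGCCAATGCGCCGCCTTCATCGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAG
>sim00006_r
TTTCTAGCTGCCTGGATTCCAGAGACAGGAAGAAATCATCTGTCAGCCCGGATATCTCAACATGCAGGAAGCTGGATTAAAAGATATCAGCGAGCGAGCTGGCCGATTCACAATAGACAACGCGAAGGGGCCATAGGGCACGTTCACTCCGTGAGCTACCGTGCAGAGTCACTACTTGACGCGTACGGCCGCAACTTCACGACACGGGTAATGCGGCCTAATGGTGACCGTAAAGATCACCATTGGGGAACCGGGCTATGCGCCAGCAGCCCGGCCGAGGCCTACTTCGGAGGCGGTCATGACAGAGCTAACCTGACCAAACAGACAGAGACTCGCCGGCGTGA
>sim00007_r
GCCCCATCTGTAAGTGAGAGTCACAATGGCAATAAGAGACCACGGCTCGACGAACCGACTCCTGAAATCCCCGTTTATGGCCACAGGGGCGGAGCTTCGATCGAGAAATTTCTCCTATCTTATGAGCCTCGAAGGAGAAGAGGTACCGGGGGCATCCGCGCGACTCCCGTACTAGTGTCCGGTGTGAGGAACCCTGCCGAAGCCGCAATGACAATAACTTCCCAAAAAATGTCCCATCTGACAAGACAGCTTCGAAGCTGCGCCGTTATACGGTGTTTGGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAG
>sim00008_r
GCCAACTTTCGCTACAATCCAGGAGCCGTGCGTTCAAATCGCAACGTACATCGAGCAGTGTTAAGCCGCCGGAATAACATGGTCTCTCATACAATTAGTTTAGGAACCAGACGTATAAGGCTGCAAGGATCGAATTTGCAACCAGTCATTTCTTTGACAGGTGCAACGCGTCAGGCCGACCGAGCATCCTCCTTCGATTTAGAACACTTCGAGAAAGGATACAGTTCTACCGCCAAGAATGTCAGATATATCCTTCATTGCGCCCAGGAGTACGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAG
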