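name	chain	v_call	j_call	constant	v_trim	j_trim	inserted_nt	full_nt	junction_nt	junction_aa	v_domain_start	v_domain_end	junction_start	junction_end	insert_start	insert_end	leader_len	constant_len
sim00001	alpha	TRAV3*01	TRAJ2*01	TRAC*01	3	1	T	ATGCGTGATGATCCAGACGATGGTAGGACGAGCCTCCCGACTCAGAATCGGTACGGCATTGAAAACTACGCCGCCTCTACGCTACTAATTGGAACCAACACGGAACGAATGGTCAGGGATGGAACTCCCGGGCGGATAGATAATCATTGGCCCTATCCCCTCATGGCCGATTTTCCCACCATTTTCATGTCGCCTTTAAACCTCCTTTTTATAGCGATGAACGTGGGTTCCGAGCCTTACTCATATAGCCGCTTACCAGACGTGATTCTGATCGGCCATCGCCCTGAACGTACCAAAAGGAGCCAATGCGCCGCCTACTACGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAGCGTCCCTAAACAAAGTCGGACTCATTTGCACCTGAGAGACCCAGCCAACTATCCCCCGAGCAGCAGACTGACTGCATCAGTGTTGAGGGCCTTTCGACTGTAA	TGCGCCGCCTACTACGGCAACACCTTC	CAAYYGNTF	49	369	307	333	316	316	48	123
sim00002	beta	TRBV2*02	TRBJ1-2*01	TRBC1*01	4	3	TTCCTATTCTGCTGCGAGGCGA	ATGCATTTTAGCGAGTTGTTAGGCGCGAATGGGGGCTCTAGTCCAACTCCAAAGCTCGGAATAGAATTCATTTTAACCGTGATCCATAGGTATGAATACTCAGCGATTCCACGCGTTTACTATCCGCTGGTAGAGTTACAACATAGACCACAGCCCCCACCGGTACCCATATACAACGTCGCAGCGGCGTACGCTACAGGATTGCGCCGAAAGACCGTAGATCAAGCGGTTCCGTCCGTTCGCATAAGAAAGGCGCGCTTCAAATATGGTTGGTCCATGTCTCTAAGAGTGTTTAGCTACGCCCTTTGCGCCAGTTCCTATTCTGCTGCGAGGCGATACGGCTACACCTGGGGAATCGGTATTTACCAGATGGGAGCCAATGGGGCCACAGAGACTCGCCGGCGTGAGCCGAAAACCGGTTGGACTGACACAAAGAGCCGATACATAGTTCGCATGTTTCTTGCAGGTGCGATACGAAGCATAAAGATTGCCACGGCGACTAAGACCTAA	TGCGCCAGTTCCTATTCTGCTGCGAGGCGATACGGCTACACCTGG	CASSYSAARRYGYTW	49	387	307	351	315	336	48	123
sim00003	alpha	TRAV2*01	TRAJ2*01	TRAC*01	1	3	CTACATG	ATGTTTTTCGAACAAACTCAGCGAAGCGGGCTTACTGGATTCATCATAGCCCCATCTGTAAGTGAGAGTCACAATGGCAATAAGAGACCACGGCTCGACGAACCGACTCCTGAAATCCCCGTTTATGGCCACAGGGGCGGAGCTTCGATCGAGAAATTTCTCCTATCTTATGAGCCTCGAAGGAGAAGAGGTACCGGGGGCATCCGCGCGACTCCCGTACTAGTGTCCGGTGTGAGGAACCCTGCCGAAGCCGCAATGACAATAACTTCCCAAAAAATGTCCCATCTGACAAGACAGCTTCGAAGCTGCGCCGTGAGCTACATGTACGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAGCGTCCCTAAACAAAGTCGGACTCATTTGCACCTGAGAGACCCAGCCAACTATCCCCCGAGCAGCAGACTGACTGCATCAGTGTTGAGGGCCTTTCGACTGTAA	TGCGCCGTGAGCTACATGTACGGCAACACCTTC	CAVSYMYGNTF	49	375	307	339	318	324	48	123
sim00004	beta	TRBV1*01	TRBJ1-1*01	TRBC1*01	0	0	TCA	ATGCGAATGCGGACAAGGATAAATCATAGAGGGTCAAGATCTATCATATTTCTAGCTGCCTGGATTCCAGAGACAGGAAGAAATCATCTGTCAGCCCGGATATCTCAACATGCAGGAAGCTGGATTAAAAGATATCAGCGAGCGAGCTGGCCGATTCACAATAGACAACGCGAAGGGGCCATAGGGCACGTTCACTCCGTGAGCTACCGTGCAGAGTCACTACTTGACGCGTACGGCCGCAACTTCACGACACGGGTAATGCGGCCTAATGGTGACCGTAAAGATCACCATTGGGGAACCGGGCTATGCGCCAGCAGCTCAAACACCGAGGCCTACTTCGGAGGCGGTCATGACAGAGCTAACCTGACCAAACAGACAGAGACTCGCCGGCGTGAGCCGAAAACCGGTTGGACTGACACAAAGAGCCGATACATAGTTCGCATGTTTCTTGCAGGTGCGATACGAAGCATAAAGATTGCCACGGCGACTAAGACCTAA	TGCGCCAGCAGCTCAAACACCGAGGCCTACTTC	CASSSNTEAYF	49	375	307	339	319	321	48	123
sim00005	alpha	TRAV3*01	TRAJ2*01	TRAC*01	3	5	TTCAT	ATGCGTGATGATCCAGACGATGGTAGGACGAGCCTCCCGACTCAGAATCGGTACGGCATTGAAAACTACGCCGCCTCTACGCTACTAATTGGAACCAACACGGAACGAATGGTCAGGGATGGAACTCCCGGGCGGATAGATAATCATTGGCCCTATCCCCTCATGGCCGATTTTCCCACCATTTTCATGTCGCCTTTAAACCTCCTTTTTATAGCGATGAACGTGGGTTCCGAGCCTTACTCATATAGCCGCTTACCAGACGTGATTCTGATCGGCCATCGCCCTGAACGTACCAAAAGGAGCCAATGCGCCGCCTTCATCGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAGCGTCCCTAAACAAAGTCGGACTCATTTGCACCTGAGAGACCCAGCCAACTATCCCCCGAGCAGCAGACTGACTGCATCAGTGTTGAGGGCCTTTCGACTGTAA	TGCGCCGCCTTCATCGGCAACACCTTC	CAAFIGNTF	49	369	307	333	316	320	48	123
sim00006	beta	TRBV1*01	TRBJ1-1*01	TRBC1*01	1	4	CCCGG	ATGCGAATGCGGACAAGGATAAATCATAGAGGGTCAAGATCTATCATATTTCTAGCTGCCTGGATTCCAGAGACAGGAAGAAATCATCTGTCAGCCCGGATATCTCAACATGCAGGAAGCTGGATTAAAAGATATCAGCGAGCGAGCTGGCCGATTCACAATAGACAACGCGAAGGGGCCATAGGGCACGTTCACTCCGTGAGCTACCGTGCAGAGTCACTACTTGACGCGTACGGCCGCAACTTCACGACACGGGTAATGCGGCCTAATGGTGACCGTAAAGATCACCATTGGGGAACCGGGCTATGCGCCAGCAGCCCGGCCGAGGCCTACTTCGGAGGCGGTCATGACAGAGCTAACCTGACCAAACAGACAGAGACTCGCCGGCGTGAGCCGAAAACCGGTTGGACTGACACAAAGAGCCGATACATAGTTCGCATGTTTCTTGCAGGTGCGATACGAAGCATAAAGATTGCCACGGCGACTAAGACCTAA	TGCGCCAGCAGCCCGGCCGAGGCCTACTTC	CASSPAEAYF	49	372	307	336	318	322	48	123
sim00007	alpha	TRAV2*01	TRAJ2*01	TRAC*01	4	6	TATACGGTGTTTG	ATGTTTTTCGAACAAACTCAGCGAAGCGGGCTTACTGGATTCATCATAGCCCCATCTGTAAGTGAGAGTCACAATGGCAATAAGAGACCACGGCTCGACGAACCGACTCCTGAAATCCCCGTTTATGGCCACAGGGGCGGAGCTTCGATCGAGAAATTTCTCCTATCTTATGAGCCTCGAAGGAGAAGAGGTACCGGGGGCATCCGCGCGACTCCCGTACTAGTGTCCGGTGTGAGGAACCCTGCCGAAGCCGCAATGACAATAACTTCCCAAAAAATGTCCCATCTGACAAGACAGCTTCGAAGCTGCGCCGTTATACGGTGTTTGGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAGCGTCCCTAAACAAAGTCGGACTCATTTGCACCTGAGAGACCCAGCCAACTATCCCCCGAGCAGCAGACTGACTGCATCAGTGTTGAGGGCCTTTCGACTGTAA	TGCGCCGTTATACGGTGTTTGGGCAACACCTTC	CAVIRCLGNTF	49	375	307	339	315	327	48	123
sim00008	alpha	TRAV1*01	TRAJ2*01	TRAC*01	6	3	CAGGAG	ATGTATAGCACCCGGCTAACGCGAGAAGTTTCTCGAGATTTCCCTCAAGCCAACTTTCGCTACAATCCAGGAGCCGTGCGTTCAAATCGCAACGTACATCGAGCAGTGTTAAGCCGCCGGAATAACATGGTCTCTCATACAATTAGTTTAGGAACCAGACGTATAAGGCTGCAAGGATCGAATTTGCAACCAGTCATTTCTTTGACAGGTGCAACGCGTCAGGCCGACCGAGCATCCTCCTTCGATTTAGAACACTTCGAGAAAGGATACAGTTCTACCGCCAAGAATGTCAGATATATCCTTCATTGCGCCCAGGAGTACGGCAACACCTTCGGAAGTGGTAACCCAAGTCCCAGTATCGATATGCACACTCCGGCACCCGGGGGTAGCGTCCCTAAACAAAGTCGGACTCATTTGCACCTGAGAGACCCAGCCAACTATCCCCCGAGCAGCAGACTGACTGCATCAGTGTTGAGGGCCTTTCGACTGTAA	TGCGCCCAGGAGTACGGCAACACCTTC	CAQEYGNTF	49	369	307	333	313	318	48	123
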