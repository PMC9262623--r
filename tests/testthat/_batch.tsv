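name	alpha_v_call	alpha_j_call	alpha_junction_aa	beta_v_call	beta_j_call	beta_junction_aa
sim00001	TRAV3*01	TRAJ2*01	CAAYYGNTF	NA	NA	NA
sim00002	NA	NA	NA	TRBV2*02	TRBJ1-2*01	CASSYSAARRYGYTW
sim00003	TRAV2*01	TRAJ2*01	CAVSYMYGNTF	NA	NA	NA
sim00004	NA	NA	NA	TRBV1*01	TRBJ1-1*01	CASSSNTEAYF
sim00005	TRAV3*01	TRAJ2*01	CAAFIGNTF	NA	NA	NA
sim00006	NA	NA	NA	TRBV1*01	TRBJ1-1*01	CASSPAEAYF
sim00007	TRAV2*01	TRAJ2*01	CAVIRCLGNTF	NA	NA	NA
sim00008	TRAV1*01	TRAJ2*01	CAQEYGNTF	NA	NA	NA
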