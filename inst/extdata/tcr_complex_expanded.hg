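T 0 directed
T 1 undirected
V TCR TCR
V alphabeta alphabeta
V alpha alpha
V beta beta
V gammaepsilon gammaepsilon
V gamma gamma
V epsilon1 epsilon
V deltaepsilon deltaepsilon
V delta delta
V epsilon2 epsilon
V zetazeta zetazeta
V zeta1 zeta
V zeta2 zeta
V ITAM_g ITAM
V Y_g_1 Y ~U,P
V Y_g_2 Y ~U,P
V ITAM_d ITAM
V Y_d_1 Y ~U,P
V Y_d_2 Y ~U,P
V PRS_e1 PRS
V ITAM_e1 ITAM
V Y188_e1 Y ~U,P
V Y199_e1 Y ~U,P
V PRS_e2 PRS
V ITAM_e2 ITAM
V Y188_e2 Y ~U,P
V Y199_e2 Y ~U,P
V ITAM_z1_1 ITAM
V Y_z1_1_1 Y ~U,P
V Y_z1_1_2 Y ~U,P
V ITAM_z1_2 ITAM
V Y_z1_2_1 Y ~U,P
V Y_z1_2_2 Y ~U,P
V ITAM_z1_3 ITAM
V Y_z1_3_1 Y ~U,P
V Y_z1_3_2 Y ~U,P
V ITAM_z2_1 ITAM
V Y_z2_1_1 Y ~U,P
V Y_z2_1_2 Y ~U,P
V ITAM_z2_2 ITAM
V Y_z2_2_1 Y ~U,P
V Y_z2_2_2 Y ~U,P
V ITAM_z2_3 ITAM
V Y_z2_3_1 Y ~U,P
V Y_z2_3_2 Y ~U,P
E TCR alphabeta 0
E alphabeta alpha 0
E alphabeta beta 0
E alpha beta 1
E TCR gammaepsilon 0
E gammaepsilon gamma 0
E gammaepsilon epsilon1 0
E gamma epsilon1 1
E TCR deltaepsilon 0
E deltaepsilon delta 0
E deltaepsilon epsilon2 0
E delta epsilon2 1
E TCR zetazeta 0
E zetazeta zeta1 0
E zetazeta zeta2 0
E zeta1 zeta2 1
E gamma ITAM_g 0
E ITAM_g Y_g_1 0
E ITAM_g Y_g_2 0
E delta ITAM_d 0
E ITAM_d Y_d_1 0
E ITAM_d Y_d_2 0
E epsilon1 PRS_e1 0
E epsilon1 ITAM_e1 0
E PRS_e1 Y188_e1 0
E ITAM_e1 Y188_e1 0
E ITAM_e1 Y199_e1 0
E epsilon2 PRS_e2 0
E epsilon2 ITAM_e2 0
E PRS_e2 Y188_e2 0
E ITAM_e2 Y188_e2 0
E ITAM_e2 Y199_e2 0
E zeta1 ITAM_z1_1 0
E ITAM_z1_1 Y_z1_1_1 0
E ITAM_z1_1 Y_z1_1_2 0
E zeta1 ITAM_z1_2 0
E ITAM_z1_2 Y_z1_2_1 0
E ITAM_z1_2 Y_z1_2_2 0
E zeta1 ITAM_z1_3 0
E ITAM_z1_3 Y_z1_3_1 0
E ITAM_z1_3 Y_z1_3_2 0
E zeta2 ITAM_z2_1 0
E ITAM_z2_1 Y_z2_1_1 0
E ITAM_z2_1 Y_z2_1_2 0
E zeta2 ITAM_z2_2 0
E ITAM_z2_2 Y_z2_2_1 0
E ITAM_z2_2 Y_z2_2_2 0
E zeta2 ITAM_z2_3 0
E ITAM_z2_3 Y_z2_3_1 0
E ITAM_z2_3 Y_z2_3_2 0
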