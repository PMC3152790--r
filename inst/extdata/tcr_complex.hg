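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
V PRS_e1 PRS
V ITAM_e1 ITAM
V Y188_e1 Y ~U,P
V Y199_e1 Y ~U,P
E TCR alphabeta 0
E alphabeta alpha 0
E alphabeta beta 0
E TCR gammaepsilon 0
E gammaepsilon gamma 0
E gammaepsilon epsilon1 0
E TCR deltaepsilon 0
E deltaepsilon delta 0
E deltaepsilon epsilon2 0
E TCR zetazeta 0
E zetazeta zeta1 0
E zetazeta zeta2 0
E epsilon1 PRS_e1 0
E epsilon1 ITAM_e1 0
E PRS_e1 Y188_e1 0
E ITAM_e1 Y188_e1 0
E ITAM_e1 Y199_e1 0
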