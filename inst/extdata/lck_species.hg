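T 0 directed
T 1 undirected
V Lck Lck
V SH3 SH3
V SH2 SH2
V Y505 Y505 ~U,P =P
V PTK PTK
V Y192 Y192 ~U,P =U
V Y394 Y394 ~U,P =U
E Lck SH3 0
E Lck SH2 0
E Lck Y505 0
E Lck PTK 0
E SH2 Y192 0
E PTK Y394 0
E SH2 Y505 1
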