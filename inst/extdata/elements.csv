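"symbol","z","a_weight","k_edge_keV"
"H",1,1.008,0
"C",6,12.011,0
"N",7,14.007,0
"O",8,15.999,0
"Na",11,22.99,0
"Mg",12,24.305,0
"P",15,30.974,0
"S",16,32.06,0
"Ca",20,40.078,0
"Ba",56,137.327,37.4
"Ta",73,180.948,67.4
"Bi",83,208.98,90.526
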