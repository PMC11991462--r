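- name: bone
  density_g_cm3: 1.92
  weight_fractions:
    H: 0.034
    C: 0.155
    'N': 0.042
    O: 0.435
    Na: 0.001
    Mg: 0.002
    P: 0.103
    S: 0.003
    Ca: 0.225
- name: PEEK
  density_g_cm3: 1.32
  formula: C19H12O3
  elastic_modulus_GPa: 4.0
- name: PEEK-HA
  density_g_cm3: 1.68
  weight_fractions:
    C: 0.633249856054
    H: 0.033966151754
    O: 0.215998042564
    Ca: 0.079787858819
    P: 0.036998090809
  elastic_modulus_GPa: 5.2
- name: PEEK-BaSO4
  density_g_cm3: 1.52
  weight_fractions:
    C: 0.633249856054
    H: 0.033564803574
    O: 0.188027381138
    Ba: 0.117683807304
    S: 0.027474151931
  elastic_modulus_GPa: 5.0
- name: PEEK-Bi2O3
  density_g_cm3: 3.84
  weight_fractions:
    C: 0.633249856054
    H: 0.033564803574
    O: 0.153786812182
    Bi: 0.17939852819
  elastic_modulus_GPa: 10.5
- name: PEEK-Ta
  density_g_cm3: 4.65
  weight_fractions:
    C: 0.633249856054
    H: 0.033564803574
    O: 0.133185340372
    Ta: 0.2
  elastic_modulus_GPa: 11.0
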