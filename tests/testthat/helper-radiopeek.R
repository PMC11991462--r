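# shared fixtures for the test suite
mats <- study_materials()
AVOGADRO <- 6.02214076e23

# atomic weights used by independent arithmetic oracles in the tests
AW <- c(H = 1.008, C = 12.011, O = 15.999, S = 32.06, Ba = 137.327)
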