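# fluorine substituent
natoms = 1
atom1.element = F
atom1.dist = 1.390
atom1.angle = 109.47
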