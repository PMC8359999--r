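# methyl: one rotamer torsion (H-C-C-ring), remaining H at fixed offsets
natoms = 4
atom1.element = C
atom1.dist = 1.530
atom1.angle = 109.47
atom2.element = H
atom2.parent = 1
atom2.dist = 1.090
atom2.angle = 109.47
atom2.torsion = rot
atom3.element = H
atom3.parent = 1
atom3.dist = 1.090
atom3.angle = 109.47
atom3.torsion = +120
atom4.element = H
atom4.parent = 1
atom4.dist = 1.090
atom4.angle = 109.47
atom4.torsion = +240
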