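# hydroxyl: one rotamer torsion (H-O-C-ring)
natoms = 2
atom1.element = O
atom1.dist = 1.430
atom1.angle = 109.47
atom2.element = H
atom2.parent = 1
atom2.dist = 0.960
atom2.angle = 104.50
atom2.torsion = rot
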