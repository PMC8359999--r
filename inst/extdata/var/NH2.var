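# amino: one rotamer torsion, second H at a fixed offset
natoms = 3
atom1.element = N
atom1.dist = 1.470
atom1.angle = 109.47
atom2.element = H
atom2.parent = 1
atom2.dist = 1.010
atom2.angle = 107.00
atom2.torsion = rot
atom3.element = H
atom3.parent = 1
atom3.dist = 1.010
atom3.angle = 107.00
atom3.torsion = +120
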