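# methoxy: two rotamer torsions (C-O-C-ring and methyl spin)
natoms = 5
atom1.element = O
atom1.dist = 1.430
atom1.angle = 109.47
atom2.element = C
atom2.parent = 1
atom2.dist = 1.430
atom2.angle = 111.00
atom2.torsion = rot
atom3.element = H
atom3.parent = 2
atom3.dist = 1.090
atom3.angle = 109.47
atom3.torsion = rot
atom4.element = H
atom4.parent = 2
atom4.dist = 1.090
atom4.angle = 109.47
atom4.torsion = +120
atom5.element = H
atom5.parent = 2
atom5.dist = 1.090
atom5.angle = 109.47
atom5.torsion = +240
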