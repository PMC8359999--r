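# hydroxymethyl: two rotamer torsions (O-C-C-ring and H-O-C-C)
natoms = 5
atom1.element = C
atom1.dist = 1.530
atom1.angle = 109.47
atom2.element = O
atom2.parent = 1
atom2.dist = 1.430
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
atom5.element = H
atom5.parent = 2
atom5.dist = 0.960
atom5.angle = 104.50
atom5.torsion = rot
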