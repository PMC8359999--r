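---
title: "Ring puckering coordinates and Monte Carlo conformer generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring puckering coordinates and Monte Carlo conformer generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puckermc)
```

## The model

A saturated N-membered ring (N = 5, 6, 7) deviates from planarity in N - 3
independent ways. puckermc describes that space with the classic puckering
coordinates: out-of-plane displacements $z_j$ of the ring atoms from a mean
plane through the ring's geometric centre, projected onto low-order Fourier
harmonics of the atom index,

$$q_m \cos\varphi_m = \sqrt{2/N}\sum_j z_j \cos\!\big(2\pi m (j-1)/N\big),
\qquad
q_m \sin\varphi_m = -\sqrt{2/N}\sum_j z_j \sin\!\big(2\pi m (j-1)/N\big),$$

for $m = 2, \dots, \lfloor (N-1)/2 \rfloor$, plus, for even N, the
alternating-sum coordinate $q_{N/2} = N^{-1/2}\sum_j (-1)^{j-1} z_j$. For
six-membered rings the polar form $Q = (q_2^2+q_3^2)^{1/2}$,
$\theta = \arccos(q_3/Q)$ places every conformation on a sphere whose poles
are the two chairs and whose equator holds the boats and skew-boats. Ring
atoms are numbered with the anomeric carbon as position 1 and the
heteroatom as position N, consecutive around the ring.

The mean plane is not just "the plane through the centre": its orientation
is fixed by requiring the first-harmonic sine and cosine projections of the
$z_j$ to vanish. Only on such displacements are the projections above
well-defined, so `mean_plane_displacements()` implements the full
construction (centre, then the normal from the cross product of the two
first-harmonic direction sums). The result is rigid-motion invariant and the
two orientation conditions hold to machine precision.

### Phase conventions

Two phase conventions coexist in practice. The package default is the
two-argument arctangent of $(A_m, B_m)$ mapped to $[0^\circ, 360^\circ)$;
the conformer catalog and all classification use it. Quantum-chemistry
scan interfaces that expose only `SQRT` and `ACOS` instead use the
reconstruction

$$\varphi_m = \frac{A_m}{\sqrt{A_m^2+\varepsilon}}
\arccos\!\frac{B_m}{\sqrt{A_m^2+B_m^2}} + 180^\circ,
\qquad \varepsilon = 10^{-6},$$

available as `phase_angle(..., mode = "paper")` and embedded in the text
emitted by `emit_gic_definitions()`. Away from the $A_m \approx 0$ seam the
two conventions differ by a constant 180 degrees; within
$|A_m| \lesssim \sqrt{\varepsilon}$ the smoothed sign factor departs from
$\pm 1$ and the arccos form is deliberately only approximate (that is what
the guard is for). The printed form of the expression is ambiguous about
whether the denominator carries a square root; dimensional analysis favours
$\sqrt{A_m^2+\varepsilon}$ (a smoothed sign function), which is what the
package implements. Inverting a paper-mode state uses the stored $A_m, B_m$
projections directly, so round trips are exact in either mode.

### Hemisphere and naming conventions

Conformer names follow the carbohydrate convention: ring positions above
the reference plane are written before the family letter, positions below
after it, and the heteroatom position is rendered by its element symbol
("O" by default). Two side conventions are fixed once:

* For N = 6 and 7, "above" corresponds to a *negative* mean-plane
  displacement. This makes $\theta = 0$ (atom 1 displaced positive) the
  ${}^4C_1$ chair, the layout every pyranose Mercator chart uses, and
  reproduces the standard name sets: the six boats $B_{1,4}, {}^{2,5}B,
  B_{3,O}, {}^{1,4}B, B_{2,5}, {}^{3,O}B$, the six skew-boats
  ${}^1S_3, {}^5S_1, {}^2S_O, {}^1S_5, {}^OS_2, {}^3S_1$, twelve envelopes
  and twelve half-chairs on the $\theta = 54.74^\circ/125.26^\circ$
  tetrahedral bands.
* For N = 5 the envelope/twist parity is anchored constructively: at
  $\varphi_2 = 0$ the atom with maximal positive displacement is atom 1 and
  the point is an envelope. Envelopes sit on even multiples of
  18 degrees, twists on odd ones.

Skew-boat names need a tie-break because four atoms are equally displaced:
the package names the meta (1,3-related) cross-side pair that contains the
lowest-numbered carbon, which is exactly the choice behind the standard six
names. Chairs name the out-of-plane para pair containing atom 1.

### Seven-membered rings

The four-dimensional $(q_2, \varphi_2, q_3, \varphi_3)$ space is reduced,
following septanose practice, to three $(\varphi_2, \varphi_3)$ planes at
relative $q_3$ amplitudes 0.6 (chair/twist-chair), 0.0 (boat/twist-boat)
and 0.4 (sofa families), the amplitudes being read on the normalized
$(q_2^2+q_3^2)^{1/2} = 1$ sphere. Plane boundaries for classification sit
at the midpoints 0.2 and 0.5. On the $q_3 = 0$ plane the structure is
independent of $\varphi_3$ (the "harp" degeneracy: boats and twist-boats
are strings at fixed $\varphi_2$), so classification there uses $\varphi_2$
alone, with 14 B and 14 TB strings alternating every
$360^\circ/28$. On the other two planes the package places 28 stations
each: mirror-symmetric stations $(\varphi_2, \varphi_3) = (2\tau, 3\tau)$
with $\tau = k \cdot 360^\circ/14$ (families C and S) and
$C_2$-symmetric stations offset by $(90^\circ, 90^\circ)$ (families TC, and
TS/SB alternating). The station grid and the constructive labeller (up to
two extreme atoms per side, within 80% of the maximal displacement) are
package conventions: the septanose literature fixes the plane amplitudes
and family letters but not a universal grid, and the names should be read
as chart coordinates rather than as literature-harmonized labels.

## Building geometries

`build_ring_geometry()` turns a puckering state into Cartesian coordinates
with exact template bond lengths. The out-of-plane part is the inverse
transform; the in-plane part places all atoms on one circle of radius
$\rho$, each edge subtending $2\arcsin(c_j/2\rho)$ where
$c_j^2 = L_j^2 - (z_{j+1}-z_j)^2$, and solves the closure condition
$\sum_j \Delta\beta_j = 2\pi$ for $\rho$ by a bracketed one-dimensional
root search (tolerance $10^{-12}$). Because the $z_j$ are imposed exactly
and the index-based orthogonality conditions make the $z = 0$ plane the
puckering mean plane of the result, the forward transform recovers the
requested state to round-off, far inside the documented contract
(bonds within $5\times10^{-3}$ Å, state within $10^{-3}$). In-plane
placement runs clockwise seen from $+z$ so the displacement signs are
preserved rather than mirrored. Amplitudes are capped at 0.9 Å; beyond
that an edge's out-of-plane rise can exceed its bond length and the
builder reports which edge failed. Endocyclic bond *angles* are emergent
(the template's angle column is a target used for exocyclic placement
geometry, not a hard constraint); at the default amplitudes they stay well
inside the chemically sensible 85-135 degree window.

Default amplitudes are 0.40, 0.55 and 0.75 Å for N = 5, 6, 7: typical
total puckering amplitudes of furanose, pyranose and septanose rings.
Default bond lengths come from standard covalent radii (C-C 1.54, C-O
1.43, C-S 1.82, C-N 1.47, C-B 1.57, C-P 1.85 Å), overridable per template.

### Dihedral libraries

A ring conformation is equally well described by its N - 3 sequential
endocyclic dihedrals $D_k$ over atoms $(k, k+1, k+2, k+3)$ — the quantity
the Z-matrix actually consumes. `build_dihedral_library()` tabulates
$D_1 \dots D_{N-3}$ for every canonical conformer of a template from the
idealized geometry above. This replaces scan libraries derived from
DFT-optimized geometries: idealized libraries are deterministic, free of a
quantum-chemistry dependency, and exact for the stated bond lengths, but
they ignore the template-specific relaxation a real scan would show
(heteroatom-adjacent angles opening, amplitude varying around the
itinerary). Externally computed libraries in the per-dihedral
`N-x-H-y-X-D#.txt` text layout can be imported with `read_library_files()`
and passed to the sampler unchanged; `write_library_files()` emits the
same layout.

### Z-matrices and substituents

`attach_substituents()` assembles the molecule in a fixed order — ring
atoms, heteroatom hydrogens (or the two sulfone oxygens), substituents by
position, filling hydrogens — so output files are reproducible. Each ring
carbon offers two tetrahedral slots at $\pm 120^\circ$ from the other ring
neighbour about the bond to the previous atom; a substituent claims the
slot whose realized side of the mean plane matches its `"up"`/`"down"`
request (evaluated on the reference conformation; at extreme ring
conformations a slot's axial/equatorial character changes, which is a
property of Z-matrix sampling itself, not of the builder). Group internal
coordinates ship as plain-text `.var` tables (`inst/extdata/var/`) with a
three-token torsion grammar: `rot` opens a new rotamer variable, `+120`
rides on the latest rotamer at a fixed offset, a bare number is fixed.
Heteroatom hydrogens on NH/PH rings ride on the discrete `HF1` variable
whose value is exactly $-120$ or $+120$ relative to the ring-neighbour
torsion — the axial/equatorial coin flip.

## The sampler

One conformer = one uniform draw of a library entry (uniform over canonical
conformations, *not* over puckering phase space — the sampling measure the
workflow defines), one uniform torsion in $[-180^\circ, 180^\circ]$ per
rotamer, and the $\pm 120$ flip where applicable. The generator is R's
default Mersenne-Twister seeded explicitly; the seed (given or
entropy-derived) is recorded in the batch and its run log, so every run is
replayable and identical seeds give byte-identical output files. There is
no energy model and no Metropolis step: the method is pure random
generation, and physically strained structures are expected output. The
`clash_check()` remedy flags any non-bonded, non-geminal atom pair closer
than 0.7 Å — a threshold chosen to catch genuinely overlapping atoms (the
documented failure mode of random torsions on crowded rings) while leaving
strained-but-valid conformers alone. Policies: `flag` (default, emit
everything), `drop` (resample, give up after $100\times$ the requested
count), `keep` (skip the test). With five random hydroxyl/hydroxymethyl
torsions, a majority of raw alpha-D-glucose conformers carry at least one
sub-0.7 Å contact; that rate is a property of the method, and the flag
column is how downstream filtering is meant to happen.

## Degenerate inputs and tie-breaks

* All-zero amplitudes: phases are reported as 0 with an explicit planar
  flag; classification below the `min_amplitude` threshold (default
  0.05 Å) returns `"planar"` instead of an arbitrary label.
* `phase_angle(0, 0)` returns 0 (standard) / 180 (paper) by convention.
* Classification ties break to the first catalog entry in the
  deterministic enumeration order.
* Collinear or coincident ring atoms raise an error rather than produce a
  meaningless plane.

## What the tests do and do not show

The suite validates the mathematics (independent brute-force oracle for
the projections, $10^{-6}$ round trips over 1000 random states per ring
size, rigid-motion invariance, the $2\pi m/N$ relabelling covariance),
the taxonomy (20 = 10 E + 10 T, 38 = 2 C + 6 B + 6 S + 12 E + 12 H,
idempotent classification of all 142 canonical states, the harp
degeneracy), the builder contract over all 21 heteroatom/ring-size
templates, sampler determinism and bounds at the 500-conformer scale of
the worked examples, draw uniformity at $n = 10^5$, and writer round
trips (with an independent PDB parser as cross-check). Batch sizes in the
tests (500 conformers, $10^5$ draws) were chosen as representative
workloads for the method. None of this certifies chemical realism:
geometries are idealized, not optimized; energies are never evaluated;
and clash flags are a distance heuristic, not a physics judgement.

## Known limitations

* Idealized bond lengths/angles stand in for optimized geometry; anomeric
  bond-length effects are not modelled.
* Exocyclic group placement is rigid tetrahedral; no pyramidalization
  relaxation.
* No oligosaccharide support: glycosidic linkage torsions are out of
  scope, as are fused/bridged rings, charged or open-shell species.
* The N = 7 sofa-plane grid and all N = 7 labels are package conventions
  (see above).
* Docking preparation emits configuration files and serial manifests only;
  ligand conversion to PDBQT and the docking itself belong to external
  tools (`prepare_ligand`, `vina`) that the package never executes.
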