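# puckermc

Conformational analysis and Monte Carlo conformer generation for small
saturated ring molecules — furanose-, pyranose- and septanose-like
monosaccharides and their S/N/SO₂/B/P-ring mimics. The package is aimed at
glycochemists and modellers who need many plausible ring conformers quickly
(for docking screens, conformer-itinerary reasoning, or as starting points
for quantum-chemistry optimization) without running any electronic-structure
or docking code themselves.

## What it computes

**Puckering coordinates.** For an N-membered ring (N = 5, 6, 7) with
out-of-plane displacements *z<sub>j</sub>* from the correctly oriented mean
plane,

  q_m cos φ_m = √(2/N) Σ_j z_j cos(2πm(j−1)/N),
  q_m sin φ_m = −√(2/N) Σ_j z_j sin(2πm(j−1)/N),

plus q_{N/2} = N^{−1/2} Σ_j (−1)^{j−1} z_j for even N, and for pyranoses the
polar form Q = √(q₂²+q₃²), θ = arccos(q₃/Q). Forward and inverse transforms,
both phase conventions (standard arctangent and the arccos/ε reconstruction
used by scan drivers without an arctan operator), and text emission of
generalized-internal-coordinate definitions are in `forward_pucker()`,
`inverse_displacements()`, `phase_angle()` and `emit_gic_definitions()`.

**Conformer taxonomy.** `enumerate_catalog()` builds the canonical catalogs —
20 conformers for five-rings (10 envelopes + 10 twists), 38 for six-rings
(2 chairs, 6 boats, 6 skew-boats, 12 envelopes, 12 half-chairs, e.g. ⁴C₁,
ᴼS₂, B₂,₅), and three (φ₂, φ₃) planes at relative q₃ = 0.6/0.0/0.4 for
seven-rings — and `classify_state()` assigns any state to its nearest
canonical conformer (or a planar flag).

**Structures.** `build_ring_geometry()` realizes any puckering state with
exact template bond lengths; `attach_substituents()` assembles the full
Z-matrix of a multifunctionalized ring (OH, CH₃, OCH₃, CH₂OH, NH₂, F, H
groups; CH₂/O/S/SO₂/NH/BH/PH heteroatoms), with the N−3 endocyclic dihedrals
and every rotatable torsion as named variables.

**Monte Carlo generation.** `generate_conformers()` draws ring conformations
uniformly from a dihedral library, one uniform torsion in [−180°, 180°] per
rotamer and the discrete ±120° N–H/P–H flip, realizes every structure and
flags steric overlap — fully reproducible from a seed.

**I/O.** Gaussian Z-matrix input, XYZ and PDB writers (plus readers for
round-tripping), `input.dat` run configurations, conformer-library text
files, and AutoDock-Vina docking preparation (config files + serial job
manifest; nothing is executed). A command-line interface ships at
`inst/exec/puckermc` with `generate`, `classify`, `catalog` and `dockprep`
subcommands.

## Worked example

```r
library(puckermc)

## classify a slightly perturbed chair
st   <- cp_pucker_state(6, Q = 0.55, theta = 5, phi2 = 100)
ring <- build_ring_geometry(ring_template(6, "O"), st)
cp_pucker(ring)
#> <cp_pucker> N = 6
#>    q2 = 0.04794, q3 = 0.5479
#>    phi2 = 100, Q = 0.55 , theta = 5
classify_state(cp_pucker(ring))
#> [1] "4C1"

## 500 random alpha-D-glucose conformers
batch <- generate_conformers(spec_alpha_d_glucose(), n_conformers = 500, seed = 42)
glance(batch)
#> # A tibble: 1 × 6
#>   n_conformers  seed n_labels n_clash n_dropped n_atoms
#>          <int> <dbl>    <int>   <int>     <int>   <int>
#> 1          500    42       38     282         0      24
head(tidy(batch), 3)
#> # A tibble: 3 × 13
#>   index label    D1    D2    D3  ROT1  ROT2   ROT3   ROT4  ROT5  ROT6 het_flip clash
#>   <int> <chr> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl>  <dbl> <dbl> <dbl>    <dbl> <lgl>
#> 1     1 3H4    48.2 -64.1 49.3  -77.0 119.    51.0   6.87  85.2 -132.       NA TRUE
#> 2     2 3,OB   37.1 -37.1 -2.08 156.  -88.0  -13.6 158.   172.  -138.       NA TRUE
#> 3     3 E4     31.3 -59.9 62.1   21.7 145.  -130.  176.   161.  -150.       NA TRUE

write_batch(batch, "glucose_conformers", format = "pdb")
```

Reading the numbers: all 38 canonical pyranose shapes were sampled
(`n_labels`), each conformer carries its three endocyclic dihedrals
(`D1`–`D3`) and six random exocyclic torsions (`ROT1`–`ROT6`); `clash = TRUE`
marks structures where random torsions brought two non-bonded atoms closer
than 0.7 Å — expected frequently for a penta-substituted ring and the reason
the flag (rather than silent emission) exists. `plot_mercator(batch)` charts
the sampled states on the puckering sphere; `autoplot(batch)` shows the
per-conformer tally.

The same workflow from the shell:

```sh
Rscript inst/exec/puckermc generate --input input.dat
Rscript inst/exec/puckermc dockprep --receptors receptors --family MANNO out/*.pdb
```

with an `input.dat` like

```
ring        = 6
heteroatom  = O
substituent = 1:OH:down
substituent = 2:OH:down
calc        = 500
seed        = 42
format      = pdb
outdir      = out
```

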