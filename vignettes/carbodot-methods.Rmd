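---
title: "Models and methods behind carbodot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind carbodot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carbodot)
```

carbodot models the interaction of small layered graphitic carbon dots
(CDs) with nucleic acids. This vignette records the models, the
conventions, the tunable parameters and the design choices, in enough
detail that a reader can judge what a passing test demonstrates — and
what it does not.

## Carbon-dot models

A CD layer is a hexagonal polyaromatic flake of ring order $n$: all
hexagons within ring distance $n-1$ of a central hexagon of a honeycomb
lattice with C–C bond 0.142 nm. This gives $6n^2$ carbons and $6n$
perimeter C–H hydrogens; $n = 2$ is coronene, $n = 3$ circumcoronene.
Layers are stacked on a common axis at the graphitic spacing of
0.35 nm, by default with an alternating half-bond lateral shift
(AB-like registry; an AA option exists, and no reported quantity is
sensitive to the choice).

Charged functional groups replace edge hydrogens: NH3+ (C–N 0.147 nm,
three tetrahedral hydrogens, formal charge +1 on N) or COO− (C–C
0.152 nm, two oxygens at 120° with C–O 0.126 nm, formal charge −1 on
one oxygen). Sites are drawn uniformly without replacement under a
user seed, so a build is bit-reproducible and different seeds give
different site sets. A `coverage` argument selects
`round(coverage * n_perimeter)` sites, where the perimeter counts both
H-bearing and junction rim carbons (18 for coronene, 30 for
circumcoronene); explicit `count` is authoritative when reproducing a
published build (9 NH3+, 11 COO−, or 26 NH3+ on the seven-layer dot).

Reported dimensions follow a vdW-augmented convention: height is the
distance between the outermost layer mean planes plus one carbon vdW
diameter (0.34 nm), diameter the largest in-plane C–C distance of the
widest layer plus 0.34 nm. The five-layer `[2,3,3,3,2]` build then
measures 1.74 nm high and 1.58 nm wide (reported as the 1.6 nm class),
the seven-layer `[3,4,5,5,5,4,3]` build 2.44 nm high. The brute-force
maximum in-plane C–C distance of the circumcoronene flake is
1.238 nm — a number the tests pin against the independent pairwise
search. Groups are placed by idealized geometry only; the models feed
geometric analysis, not force-field simulation, so no minimization is
performed.

## Nucleic-acid generator

Duplexes are assembled from embedded heavy-atom base templates in the
standard (Tsukuba-convention) base reference frame — x toward the major
groove, z along the stack — and a reduced sugar–phosphate backbone
(P, O5', C5', C4', O4', C3', O3', C2', C1'; no OP1/OP2, no O2', no
hydrogens). The backbone template was constructed once and frozen as a
package constant:

* a pentagonal sugar ring with a Cremer–Pople-style out-of-plane
  displacement whose phase is tuned so the Altona–Sundaralingam
  pseudorotation phase is 162° (C2'-endo, B form) or 18° (C3'-endo,
  A form);
* exocyclic substituents at idealized tetrahedral directions, an anti
  glycosidic torsion, O5'/O3' at canonical gamma/delta torsions;
* the phosphorus placed by *helix closure*: 0.16 nm from the previous
  residue's O3' toward this residue's O5' under the default helical
  step, which makes the assembled strand chemically continuous
  (measured O3'–P 0.159–0.163 nm on both strands) by construction.

Among the discrete orientation choices of that construction, the one
matching the radial positions of real B-DNA backbone atoms (P at
0.91 nm from the axis) was selected, and the whole template set was
rotated 180° about x so the frame z axis runs along the strand's
5'→3' direction. Because generator and analyzer share one mid-frame
(CEHS/3DNA) kernel, every helical parameter written by the generator is
recovered exactly by the analyzer on noise-free structures; tests
assert recovery within 0.3°/0.005 nm over twist 30–40° and rise
0.26–0.36 nm.

Defaults: B-DNA twist 34.3° (the 10.5 bp/turn solution value) and rise
0.338 nm; A-RNA 32.7° and 0.281 nm. The nucleosomal superhelix places
base-pair origins exactly on a left-handed helical path (radius
4.18 nm, pitch 2.39 nm, 1.7 turns — canonical nucleosome values, since
no specific ones are prescribed) with a local twist of 35.3°/step wound
about the path tangent. The curvature couples weakly into the measured
twist, so the analyzed superhelix reads ~34.9° (10.3 bp/turn) rather
than the nominal 10.2. The two-tetrad G-quadruplex mock is eight
guanines in two planar, tagged quartets 0.34 nm apart — a stacking
target with correct ring chemistry, not a realistic quadruplex (no
backbone, no ions, no loops).

Synthetic trajectories add seeded isotropic Gaussian noise per atom and
coordinate; a binding event moves the CD from 2.5 nm out along its
approach direction into the pose linearly over a fixed ten-frame
window. Frame 0 is always noise-free.

## Binding poses and the mode classifier

`place_cd_pose()` realizes the seven-label taxonomy: groove poses
approach face-on along the base-pair ±x axis to van der Waals contact
(no pair closer than 0.8 of the radius sum); the backbone pose
approaches a phosphate radially; stacking poses set the outermost flake
plane parallel to the target base/quartet plane at the stacking
distance (default 0.34 nm); unbound parks the dot beyond 2 nm.

The classifier is a deterministic decision procedure:

1. **Unbound gate** — minimum CD–NA heavy-atom distance above the
   contact cutoff (0.40 nm).
2. **Stacking** — any CD layer ring tested geometrically against
   G-tetrads, annotated unpaired bases and terminal base pairs
   (separation within 0.25–0.45 nm, normals within 30°, lateral offset
   within 0.20 nm), with precedence tetrad > unpaired > terminal.
3. **Contact counts** — nucleic-acid atoms within the cutoff of the CD
   are counted per minor-edge, major-edge and backbone name sets. A
   groove label is assigned when its count strictly dominates the
   other groove and backbone contacts do not exceed twice it.
4. **Azimuthal sector** — when contacts are backbone-dominated or
   ambiguous, the azimuth of the CD centroid in the nearest base-pair
   frame decides: within ±60° of +x is major groove, within ±60° of
   −x is minor groove, otherwise backbone.

Step 4 is the package's own operationalization and deserves its
rationale. A 1.6 nm dot physically cannot reach the floor of the
~1.2 nm-wide B-DNA minor groove: at the closest sterically allowed
approach the nearest minor-edge atom (a sugar O4') sits 0.57 nm from
the dot — beyond any defensible contact cutoff — so a pure
contact-count rule can never label minor-groove binding of a dot this
size. Position relative to the groove axes is exactly what a human
inspector uses to call these poses, it is robust (the centroid azimuth
moves little under coordinate noise), and it reduces to the count rule
whenever counts are decisive. The sector half-width (60°) and the
backbone-dominance factor (2) live in `contact_config()`.

With these rules, planted-pose recovery is exact without noise and
99% at σ = 0.05 nm over the seven modes × 20 seeds. The dominant mode
of a trajectory is the modal label over the trailing 20% of frames,
echoing tail-window averaging of long simulations. Mixed situations
(e.g. stacking while touching backbone) resolve by the stacking branch;
the full evidence record (counts, stacking geometry, azimuth, minimum
distance) is returned alongside the label.

## Interaction observables

SASA uses Shrake–Rupley with a deterministic Fibonacci point set (960
points/atom by default) and Bondi radii, probe 0.14 nm. Determinism
makes results bit-reproducible; the price is that rotational invariance
holds only to the quadrature resolution (about 1%, tested at 2%). The
default point count is converged to 0.04% against a 4× finer set on the
five-layer dot; a single carbon reproduces the analytic sphere to
1e-13 relative. Contact area is `SASA(A) + SASA(B) − SASA(A∪B)`,
clamped at zero, so larger means more contact.

Hydrogen bonds use donor–acceptor ≤ 0.35 nm and D–H···A ≥ 135° — a
common trajectory-analysis default, stated here because reasonable
tools differ. The RDF uses a non-periodic normalization (ideal-gas
shell expectation at the mean density of the partner group within the
analysis sphere), appropriate for the non-periodic synthetic systems
analyzed here; periodic-box RDFs from simulation packages will differ
near and beyond half the box length.

## Shape descriptors and nucleosome metrics

Layer planes are fit by SVD; undulation is the out-of-plane RMS.
Interlayer distances project adjacent layer centroids on the reference
(middle) layer normal; tilt is the angle to that normal. The rotation
descriptor is the in-plane angle of a layer's marker direction (layer
centroid to its lowest-serial perimeter carbon) measured against the
reference layer's marker, relative to frame 0, with the normal's sign
fixed by the internal handedness of two marker atoms — this makes all
descriptors invariant under global rigid motion (tested to 0.01°).
Detachment is flagged when an outer layer's nearest-neighbour centroid
distance exceeds 0.60 nm for at least five consecutive frames; both
numbers are conventions for a qualitatively described phenomenon.

Gyre distances take each base pair's all-atom centre of mass and the
minimum distance to any base pair more than ten positions away in
sequence. On a straight helix this equals (exclusion + 1) × rise
(3.72 nm for B-DNA defaults, reproduced to 0.1%). On the 146-bp
superhelix the minimum approximates the pitch from below: centres of
mass sit up to ~0.25 nm off the path centreline, so the closest
cross-gyre approach measures ~1.9 nm against the 2.39 nm pitch.

Per-residue RMSF superposes all frames on an alignment selection onto
the time-average structure (two passes) — isotropic noise of width σ
yields RMSF = σ√3, reproduced within 0.5% at 500 frames. Event-aligned
RMSD takes the onset of the first bound stretch persisting ≥ 10 frames,
superposes pre-window `[t0−Δ, t0)` and post-window `[t0, t0+Δ]` frames
onto the pre-event average, and reports per-residue after-minus-before
RMSD; the whole protocol (window sizes, alignment set, persistence) is
a package-defined stand-in for event-aligned analyses whose exact
published procedure is not specified.

## Problem sizes and what the tests show

The test and acceptance suites run at desk scale: 12–40 bp duplexes,
the 146-bp superhelix, trajectories of 2–500 frames, 7 × 20 planted
poses. These sizes make the suite complete in minutes on one CPU while
still exercising every code path at meaningful statistical power
(binomial noise on the 140-pose recovery is ~2%).

The generator emulates geometry, not physics: rigid templates, no
sequence-dependent energetics, no solvent or ions, no histone protein,
Gaussian rather than correlated thermal noise, and binding events that
are scheduled, not emergent. Passing tests therefore demonstrate that
the *measurement layer* is correct and self-consistent (round trips,
closed forms, planted-truth recovery) — they do not validate any claim
about real binding distributions, which require actual simulation
ensembles far beyond this package's scope.

## Known limitations

* The reduced backbone omits OP1/OP2 and O2'; groove widths and
  backbone contact counts are therefore class-accurate, not
  atom-complete.
* A-RNA uses its own frozen template but no x-displacement; its grooves
  are idealized.
* The classifier's azimuthal sector assumes a locally duplex-like
  geometry; on the quadruplex mock it falls back to raw counts.
* `bp_per_turn` on strongly bent paths folds curvature into twist at
  the few-tenths-of-a-degree level.
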