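---
title: "Multi-lattice snapshot indexing in Rodrigues-Frank space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-lattice snapshot indexing in Rodrigues-Frank space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Serial crystallography records snapshot diffraction images from a stream of
randomly oriented microcrystals. Because crystal arrival is essentially a
Poisson process, pushing the hit fraction up inevitably produces images in
which several crystals diffract at once: at a mean of one crystal per shot,
only 36.8% of images contain exactly one pattern while already 26.4% contain
more than one (`poisson_expectations()`). Conventional autoindexers assume a
single dominant lattice; `rfindex` implements a multi-lattice indexer in the
FELIX/Grainspotter family that disentangles the spots of tens of overlapping
patterns in a single step, together with a synthetic snapshot generator and a
misorientation-analysis toolkit for validating it.

## The model

**From detector to reciprocal space.** With the beam along +x and a flat
detector perpendicular to it at distance $L$, a Bragg spot at scattering
angle $2\theta$ and azimuth $\eta$ corresponds to the scattering vector
$\mathbf{g} = \mathbf{k}_{out} - \mathbf{k}_{in}$ on the Ewald sphere, with
$|\mathbf{g}| = 2\sin\theta/\lambda = 1/d$ (`peak_to_gvector()`). Spot
prediction uses a spherical partiality model: a reflection with reciprocal
point $\mathbf{q} = U B \, hkl$ is recordable when its excitation error --
the distance of $\mathbf{q}$ from the Ewald sphere -- is at most the profile
radius $r_p$ (default $0.0086\ \mathrm{nm}^{-1}$).

**Orientation geodesics.** A single observed spot $\mathbf{g}$, tentatively
assigned to reflection $\mathbf{h} = B\,hkl$, does not fix the crystal
orientation; it constrains it to the one-parameter family of rotations
mapping $\hat{\mathbf{h}}$ onto $\hat{\mathbf{g}}$. In Rodrigues-Frank (RF)
space, where a rotation by $\omega$ about $\hat{\mathbf{n}}$ is the vector
$\mathbf{r} = \hat{\mathbf{n}} \tan(\omega/2)$, this family is a straight
line: it passes through the minimal rotation (axis
$\hat{\mathbf{h}} \times \hat{\mathbf{g}}$) and runs parallel to
$\hat{\mathbf{h}} + \hat{\mathbf{g}}$, the axis of the maximal (half-turn)
solution (`geodesic_from_pair()`). The true orientation of every crystal
lies at a mutual intersection of many such lines, one per (spot, candidate
reflection) pair -- so indexing becomes the search for high-intersection
points, a Hough-style accumulation.

**Four finite charts.** RF space blows up as $\omega \to 180^\circ$, so the
search runs in a finite four-chart covering ("frustums"). As unit
quaternions, the geodesic family is a great circle of $S^3$, i.e. a 2-plane
through the origin of $\mathbb{R}^4$. Chart $k \in \{0,1,2,3\}$ holds the
rotations whose dominant quaternion component is $q_k$, with local
coordinates the remaining components divided by $q_k$; each chart domain is
then exactly the cube $[-1,1]^3$, and the central projection of the great
circle into a chart hyperplane is again a straight line. This choice (the
single most consequential design interpretation in the package) preserves
straight-line geodesics per chart, makes the four charts congruent cubes,
and renders cross-chart continuity automatic: a geodesic leaving one cube
face enters the adjoining chart's boundary voxel because dominance regions
tile the quaternion sphere. Chart 0 coordinates coincide with the RF vector
itself.

**Voxel ray tracing.** Each chart is divided into $N_v^3$ voxels. A geodesic
is clipped to each cube and walked with an exact incremental cell-boundary
DDA (Amanatides-Woo) -- not point sampling -- so visit sets are
deterministic and each voxel is incremented at most once per geodesic (the
clip of a line to a convex cube is a single segment). The per-voxel 16-bit
counters saturate at 65535, far above any realistic visit count.

## The pipeline (`index_image()`)

1. **Candidate pairing.** A (spot, reflection family) pair is kept when the
   relative magnitude mismatch satisfies
   $\bigl||\mathbf{g}|-|\mathbf{h}|\bigr|/|\mathbf{h}| \le
   \sigma\,\Delta\theta/\tan\theta$, the $2\theta$ uncertainty
   ($\Delta\theta = \sigma_{2\theta}/2$) converted to a relative magnitude
   uncertainty through the Bragg derivative and scaled by $\sigma$. One
   geodesic is traced per symmetry-equivalent member of each paired family;
   antipodal (g = -h) combinations have no finite RF anchor and are skipped.
2. **Candidate orientations.** Voxels that dominate their 26 in-chart
   neighbours and satisfy $V \ge V_{min}$ and $V \ge f_V V_{max}$ seed
   candidates. Because geodesics are traced per equivalent reflection, every
   Laue-rotation copy of a true orientation is a peak; candidates are
   therefore symmetry-deduplicated (clustered at 1.25 voxel diagonals of
   symmetry-reduced misorientation, keeping the most-visited member) before
   the refinement cap of 200 is applied.
3. **Matching.** For a candidate orientation, each spot is assigned to the
   magnitude-compatible equivalent reflection minimizing the angular
   deviation between $\hat{\mathbf{q}}$ and $\hat{\mathbf{g}}$, subject to
   (a) a pre-selection on the equivalent rotation about the lab z axis
   bringing $\mathbf{q}$ onto $\mathbf{g}$ (bound
   $\Delta\omega_{max}$), and (b) the deviation bound
   $\sqrt{\sigma_\eta^2 + \sigma_{2\theta}^2}$. Assignment is greedy by
   smallest deviation and one-to-one in both directions. The first matching
   round after voxel seeding uses the larger of this bound and 1.5 voxel
   diagonals, since the voxel discretization (about $0.7^\circ$ at
   $N_v = 300$) can exceed the user bound; after refinement the user bound
   is applied.
4. **Refinement.** Orthogonal-Procrustes (Kabsch/SVD) alignment of matched
   unit vectors, iteratively trimming matches with residual angle above
   $\max(3\sigma_\eta,\ 3\times\text{median residual})$, up to ten rounds;
   candidates left with fewer than two or only collinear matches are
   discarded as underdetermined.
5. **Acceptance.** Solutions need $n_{matched} \ge N_{min}$ and completeness
   (matched over predicted recordable spots) $\ge c_{min}$; processing in
   descending match count, a candidate whose matched-peak set overlaps an
   accepted solution by more than $u_{max}$ (normalized by the smaller set)
   is dropped as a duplicate.

### Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `n_voxels` | voxels per chart axis | -- | per scenario (300/400/600) |
| `v_min` | minimum geodesic visits to seed | counts | 30 |
| `f_v` | fraction of the maximal visit count | -- | per scenario (0.7/0.5/0.3) |
| `sigma_2theta` | scattering-angle uncertainty | deg | per scenario (0.3/0.15/0.15) |
| `sigma_eta` | azimuth uncertainty | deg | as `sigma_2theta` |
| `sigma` | scale on the magnitude tolerance | -- | 0.2 |
| `delta_omega_max` | z-rotation pre-selection bound | deg | 30 |
| `n_min` | minimum surviving matches | counts | 20 |
| `c_min` | minimum completeness | -- | 0.5 |
| `u_max` | uniqueness-overlap threshold | -- | 0.5 |
| `d_min` | resolution cutoff | nm | per scenario (0.2/0.3/0.3) |
| `r_profile` | excitation (profile) radius | nm$^{-1}$ | 0.0086 |

The per-scenario values of $N_v$, $f_V$ and
$\sigma_{2\theta} = \sigma_\eta$ are the tuned settings of the three
standard study scenarios. $\sigma = 0.2$ and $u = 0.5$ follow the settings
used for experimental lysozyme data in this algorithm family;
$\Delta\omega_{max} = 30^\circ$, $V_{min} = 30$, $N_{min} = 20$ and
$c_{min} = 0.5$ are this package's defaults, chosen once as mild,
scenario-independent guards (the $f_V V_{max}$ criterion and the
completeness test dominate them on realistic images) and not tuned against
any benchmark. Whether the pre-selection axis should be the lab vertical or
the beam axis is not determinable from the published description; it is
configurable (`omega_axis`), defaulting to the lab z axis.

## The synthetic generator

`simulate_image()` emulates a monochromatic snapshot of $N$ crystals:
uniformly random orientations (uniform unit quaternions), all
centering-allowed reflections to the resolution cutoff, spherical-partiality
recording at $r_p$, single-pixel spots on a flat square detector (110 um
pixels, 17 cm across -- a flattened stand-in for a tiled panel detector).
Three presets span the crystal systems of interest: an I-centred cubic
zeolite (a = 6.39 nm, 9000 eV, 0.090 m, 2.0 A), tetragonal hen egg-white
lysozyme (7.90 x 7.90 x 3.80 nm, 9340 eV, 0.090 m, 3.0 A) and a C-centred
monoclinic GPCR (7.28 x 4.10 x 16.77 nm, beta = 99.4 deg, 7800 eV, 0.130 m,
3.0 A). The default noise model is noise-free, matching the simulation
study the generator reproduces; Gaussian positional jitter, random peak
loss, and spurious peaks are available as options. Spots from different
crystals closer than one pixel are merged into a single doubly-provenanced
peak (bucketed by pixel-sized cells, an approximation to exact
nearest-neighbour merging that only matters at extreme spot densities).

What the generator does *not* emulate -- detector tiling and gaps,
background and peak-finding errors, bandwidth and divergence, intensity
statistics -- bounds what passing tests show: they validate the indexing
geometry and the algorithm's multi-lattice disentangling power, not
robustness to the full error budget of experimental data. Consistent with
that, simulated spot counts per crystal (e.g. about 140 for the lysozyme
scenario) agree with nominal counts for comparable full-detector
simulations only to a factor of about two, since those depend on details
this generator deliberately omits (bandwidth, tiling); the package treats
such comparisons as order-of-magnitude checks.

One observation-model subtlety: a reflection inside the partiality sphere
but off the exact Ewald surface lands on the detector along the *ray* of
$\mathbf{k}_{in} + \mathbf{q}$, so the g vector recovered from the detector
(which assumes elastic scattering) deviates from $\mathbf{q}$ by up to
$\sim r_p/|\mathbf{g}|$ radians. This is physical, not noise, and it is why
matching tolerances cannot be arbitrarily tight even on noise-free images.

## Evaluation and misorientation analysis

Found orientations are scored against ground truth by greedy one-to-one
matching in increasing symmetry-reduced misorientation, correct within a
1 degree default tolerance (`match_to_truth()`). The tolerance value is a
package choice -- no standard exists -- and results are robust
across 0.5-2 degrees because refined orientations sit well below
0.1 degree from truth while wrong solutions are tens of degrees away.

The misorientation between two orientations is the minimal rotation angle
of $U_1 S U_2^{-1}$ over the proper Laue rotations $S$
(`misorientation()`); it is symmetric in its arguments and capped by the
symmetry-dependent maximum (about 62.8 degrees for the cubic group, which
the test suite recovers by brute force over the 24 operators rather than
asserting from literature). `misorientation_survey()` collects all
within-image pairs -- the signature of crystal agglomerates is an excess of
small angles over the random baseline -- and bins the minimizing RF vectors
in 2D projections to reveal preferred sticking axes.
`random_misorientation_baseline()` is a Monte-Carlo stand-in for the
analytic random-misorientation density: equivalent in distribution, simpler
to verify, and accurate to sampling error at the default $10^5$ pairs.

## Numerical choices and degenerate inputs

* Chart ties (equal dominant quaternion components) break to the lowest
  component index; the voxel grid treats the shared face consistently in
  both adjoining charts.
* RF conversion refuses rotations within $10^{-9}$ rad of $180^\circ$
  rather than silently returning infinities; the chart covering handles
  them.
* Antipodal (g, h) pairs are degenerate (measure-zero orientation set) and
  are skipped with a count.
* Local-maxima plateaus return every plateau voxel, ordered by visits then
  (chart, linear index), so results are deterministic.
* Collinear match sets (e.g. only a Friedel pair) are rejected as
  underdetermined via the second singular value of the Procrustes cross
  matrix.
* All randomness flows through R's RNG; identical seeds give byte-identical
  images, solution streams and reports.

## Problem sizes

The shipped checks use desk-scale sizes chosen as the package's own test
protocol: the high-multiplicity precision study runs 5-6 images of 45 cubic
crystals (about 8000 spots, 2.5 million geodesics, and a 300^3-voxel x
4-chart accumulator per image, roughly 45-60 s each); single-crystal
recovery runs a handful of trials per scenario; distributional checks use
$10^4$-$10^5$ Monte-Carlo samples. A full accuracy-versus-multiplicity
sweep (many trials per point, crystal counts 1-50) is the same computation
repeated more often.

## Known limitations

* Unit-cell parameters are always given, as in the reference workflow; no
  cell search or refinement.
* Only Laue proper rotations and centering filters are applied; reflection
  conditions from screw axes / glide planes are not (they affect absent-spot
  bookkeeping, not the orientation search, and completeness denominators
  would shift by at most a few percent for the affected space groups).
* A single flat detector panel; tiled geometries must be pre-flattened to
  beam-relative metre coordinates.
* Hexagonal/trigonal Laue classes are not yet wired in (the operator
  machinery is generic; the integer-matrix check guards any addition).
* Peak lists are CSV/TSV text; no binary container formats.
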