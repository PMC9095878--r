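---
title: "Quantifying pore-forming oligomers in AFM topographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pore-forming oligomers in AFM topographs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremorph)
```

# Scope

`poremorph` quantifies membrane-inserted pore-forming protein oligomers
— gasdermin-type rings, arcs and slits — in AFM height maps, and builds
the corresponding coordinate models for image/model comparison. The
package covers five stages:

1. a synthetic topograph generator that emulates the imaging physics
   (tip convolution, slow-axis drift, scan noise);
2. preprocessing (trace/retrace averaging, plane leveling to a membrane
   baseline at 0 nm, drift unwarping, pixel-size calibration);
3. particle morphometry (maximum height, crest diameter, lumen depth,
   pre-pore/pore classification, distribution fits, track linking,
   outcome tallies);
4. stoichiometry by rotational power spectra, iterative correlation
   averaging with member rejection, and n-fold symmetrization;
5. oligomer model building from a monomer (rings by N rotations of
   360/N degrees, arcs cut from rings, slits from two arcs, linear
   chains) plus per-subunit structural metrics (head orientation angles
   tau/chi/alpha, hydrogen-bond and salt-bridge counts, C-alpha RMSD).

Every stage is testable without external data: the generator and the
monomer fixture provide ground truth with known parameters.

# The synthetic generator: what it emulates, and what it does not

A scene is a flat membrane (height 0 by convention) carrying oligomers
whose protomers are isotropic Gaussian bumps of height `subunit_height`
(default 3.4 nm, the measured protrusion of membrane-inserted
oligomers) and lateral sigma `subunit_width` on a crest circle of
diameter `crest_diameter` (default 26.3 nm, the measured ring mean;
population draws use SD 2.2 nm). Stoichiometries default to 18–36 with
the mode near 30, matching the observed range. Arcs are contiguous
subunit runs; slits are two mirrored arcs whose terminal subunits
touch. Lumens render at `lumen_depth` (0 for a plugged pre-pore; the
open-pore floor defaults to −3 nm, deliberately well past the ±2 nm
decision boundary so classification is exercised away from the
threshold edge).

The imaging model applies, in order:

* **slow-axis drift** as a pure affine stretch of the y axis (the one
  drift mode that is exactly invertible), sampled analytically so no
  resampling error enters the ground truth;
* **tip convolution** as grayscale dilation with a spherical tip —
  the imaged height at a pixel is the lowest tip-apex position that
  touches the surface. The output is pointwise ≥ the input and leaves
  flat surfaces unchanged;
* **scan noise**: per-pixel Gaussian noise plus per-scanline offsets.

All randomness derives from a single integer seed through fixed
sub-stream offsets, so scenes are bit-identical given the seed.

The generator does **not** model bilayer elasticity, tip wear or
double-tip artifacts, feedback ringing, or line-by-line polynomial
background — so green tests certify the algorithms under the stated
noise model, not robustness to every instrumental pathology of real
scans.

The protomer bump width is not a measured quantity; the default
(sigma = 1.2 nm) was chosen once so that the bumps of the largest
configured stoichiometry (36 on a 26.3 nm circle) remain resolvable at
the ≈2 nm lateral resolution at which averaged topographs and model
renders agree, and it is a free configuration parameter.

# Preprocessing choices

**Leveling.** The membrane baseline is the mode of the height
histogram with 0.05 nm bins, refined by the median of a ±0.075 nm
window; the best-fit plane is removed first, then refitted on
membrane-band pixels only so that particles covering up to roughly 40%
of the area do not tilt the estimate. Two separated near-equal modes
(a genuinely bimodal baseline, e.g. a half-covered terrace) trigger a
warning and the lower mode is chosen. Leveling is idempotent and
invariant to adding any plane.

**Unwarping.** With a known stretch the y axis is resampled by the
exact inverse using a natural cubic spline per column (sub-pixel crest
localization downstream benefits from the smoother interpolant). When
the stretch must be estimated, the package uses the second-moment
anisotropy of detected particle crest masks — for a circular object
stretched by s along y, sqrt(Iyy/Ixx) = s — which is the closed-form
maximizer of mean particle circularity. Estimates outside [0.5, 2] are
rejected as outside the drift model. On the generator's scenes the
estimator recovers a 15% stretch within 2%.

**Pixel calibration.** Ring diameters cluster by stoichiometry, so the
measured mean diameter of one stoichiometry class is matched to the
outer diameter of a built atomic model (`model_outer_diameter()` of a
ring from `build_ring()`); the reference diameter is a configuration
value because it depends on the monomer used.

# Morphometry

**Maximum height.** A literal per-pixel maximum over a noisy ROI is
biased upward by roughly two noise standard deviations (the maximum of
hundreds of noisy crest pixels), which would be a +0.3 nm artifact at
0.15 nm scan noise. The reported `max_height` is therefore the median
of per-bump apex estimates: crest local maxima are located on a
twice-box-smoothed image, a 2D Gaussian is fitted by nonlinear least
squares to the raw 5×5 neighborhood of each bump, and the median
amplitude over bumps is returned. On noiseless renders this equals the
true maximum within 0.02 nm; at 0.15 nm noise and a 2 nm tip the
ensemble bias is below 0.05 nm.

**Crest diameter.** For rings, twice the peak radius of the
azimuthally averaged radial profile about the fitted ring center, with
parabolic sub-bin refinement — robust to single-pixel noise, unlike
picking two opposing profile maxima. For arcs and slits, the maximal
crest-point separation (convex hull diameter of the crest mask).

**Ring center.** Height-weighted algebraic (Kasa) circle fit through
the crest pixels. This is exact for symmetric rings; a Nelder-Mead
profile-sharpness refinement was tried and rejected because its binned
objective allowed half-pixel drifts that leak power into off-symmetry
orders after symmetrization.

**Pore state.** An oligomer is a pore iff its lumen penetrates the
membrane by at least 2.0 nm, threshold inclusive; the lumen minimum is
taken inside 0.75 of the crest radius. The rule is monotone by
construction.

**Shape classes.** Rings close the crest circle (angular coverage
about the centroid ≥ 330 degrees and near-isotropic second moments);
slits show exactly two coverage segments totalling ≥ 300 degrees *or*
a closed but strongly elongated crest (aspect ratio > 1.25) — the
elongation clause is needed because slit arcs that touch leave angular
gaps smaller than any robust gap threshold; everything else is an arc.
This operationalizes what is a visual call in practice.

**Mobility.** Tracks are greedy nearest-neighbor links; a track is
mobile if it appears or disappears mid-series or moves more than a
configurable threshold (about one crest diameter is a sensible value;
no quantitative criterion is established in the field).

# Stoichiometry, averaging, symmetrization

The crest annulus (±25% of the crest radius) is unwrapped on a polar
grid with `n_theta = 4 * n_max` angular samples (160 for the default
search range 14–40, comfortably above Nyquist for order 40), radially
averaged, and Fourier-transformed; `power[k]` is the squared magnitude
of the k-th angular coefficient. The detected stoichiometry is the
argmax over orders 14–40 — covering the observed 18–36 with margin —
and is reported only when the peak is *distinct*.

**Distinct-peak criterion.** Defaults: peak ≥ 4× the runner-up order
and ≥ 25× the in-range median power. These were set from the measured
statistics of the two regimes the flag must separate, not from any
target rate: white-noise annuli (order powers ≈ i.i.d. exponential)
reach prominence ratios of about 3 at the 99th percentile, while
genuine rings whose crest modulation is only three times the noise sd
sit near 300 at the 1st percentile. Any choice in the wide gap between
those distributions behaves identically; both parameters remain
exposed configuration.

**Correlation averaging.** The initial reference is the member with
the highest mean pairwise correlation (the first reference is
otherwise arbitrary); each cycle aligns all members to the reference
(rotation about the reference's mass centroid after integer centroid
pre-matching, then parabolic sub-grid refinement of angle and shifts),
eliminates members correlating below 0.9, and averages the retained,
transformed members as the next reference, stopping when membership
and mean correlation stabilize. Rotating about the mass centroid
rather than the image center matters: for an off-center particle no
rotation about the image center relates two views exactly.

**Symmetrization** averages the image over rotations by multiples of
360/N using bicubic (Catmull-Rom) interpolation; bilinear interpolation
was measured to break the projection property (symmetrizing twice
moved heights by up to 0.12 nm; bicubic keeps it under 0.06 nm) and
the spectral purity of the result (off-order power < 1e-3 of the
peak).

**Model rendering** (`coords_to_topograph()`) produces the hard-sphere
top surface of the atom spheres (atom radius + probe inflation),
clipped at the membrane plane, averaging multiple frames pixel-wise —
the standard forward model for comparing simulated structures with
averaged topographs.

# Oligomer building and the surrogate energy

A ring places the monomer at radius R on the +x axis and rotates it N
times by 360/N degrees about the membrane normal, giving exact N-fold
symmetry by construction (verified atomwise to < 1e-6 nm). Arcs keep
the first M contiguous subunits. A slit rotates the second arc by 180
degrees about the membrane normal and places it so the terminal
subunits face the first arc's terminals at a configurable gap
(default: the intra-ring neighbor spacing); congruent arcs yield an
exact two-fold axis. The construction is purely rigid — arcs longer
than half their ring mesh with ring-like clearance, while shallow
facing arcs enclose a narrow slot where rigid subunit clouds can
approach closely; the steric guard (`clash_radius`) can be relaxed for
such geometries, as a downstream energy minimization would resolve
them. Linear oligomers are translated copies at fixed spacing, and at
N = 800 and fixed spacing the ring neighbor geometry agrees with the
translation within 1%.

The ring radius is selected by scanning an assembly energy over a
radius grid and refining the argmin parabolically; a monotone curve on
the grid is an error (no bracketed minimum). The default energy is a
**surrogate**, not a force field: soft-core quadratic repulsion inside
0.25 nm over all neighbor atom pairs plus a Gaussian contact
attraction (weight 30, sigma 0.6 nm) between designated interface
atoms of adjacent subunits. Its only job is to express the
clash/contact trade-off that makes an interior optimum exist; absolute
optimal radii are specific to the monomer used and are not comparable
with values obtained from force-field minimization. Two consequences
of that role shaped the fixture: the head cloud is a solid
(double-shell) ellipsoid so interpenetrating heads always raise the
repulsion — with hollow shells the landscape had spurious minima where
shells crossed — and any analytic pair potential can be supplied via
`energy_fn`, for which the closed-form optimum
R = d*/(2 sin(pi/N)) is recovered within 0.5% across N = 8–40.

# Structural metrics

Principal axes are covariance eigenvectors ordered by decreasing
eigenvalue. Signs: the first axis points toward the membrane normal,
and the second axis follows the cloud's positive third moment when the
cloud is measurably skewed along it, falling back to the radial
reference otherwise. The skew rule is what makes the frame equivariant
under rigid rotation — a fixed external reference flips the axis for
rotations beyond 90 degrees, which would fold the signed roll angle.
Degenerate leading eigenvalues are an error; a degenerate transverse
pair (collinear cloud) yields the first axis with a warning.

The head orientation is reported as tau = angle(PH1, PB1) (vertical
tilt along the membrane normal), chi = angle(PH1, PB3) (horizontal
swing), and alpha = the signed rotation of PH2 about PB1 measured from
PB3 projected into the plane perpendicular to PB1 (the zero reference,
which is otherwise a free convention). In the monomer fixture's
reference pose tau = 0, chi = 90 and alpha = 0 by construction, and a
roll of the head about the hairpin axis adds to alpha exactly
(mod 360).

Hydrogen bonds use the trajectory-analysis convention: donor-acceptor
distance ≤ 0.35 nm and hydrogen-donor-acceptor angle ≤ 30 degrees, one
count per donor-acceptor pair; when a structure carries no hydrogens,
idealized donor hydrogens are placed along the direction away from the
bonded heavy neighbors and the result is flagged. Salt bridges pair
Arg/Lys side-chain nitrogens (termini included) with Asp/Glu
carboxylate oxygens at ≤ 0.40 nm minimum heavy-atom distance, one
count per residue pair. Neither cutoff is established by the
experiments the package models; both are the field's common defaults
and are configuration. Adjacency is cyclic for rings and a chain for
arcs, slits and linear oligomers; per-subunit counts sum over both
neighbors, and multi-frame input yields per-frame series with Q1 /
median / Q3 summaries following the usual boxplot convention. Counts
on the synthetic fixture reflect its engineered contact sites only —
reproducing absolute interaction counts of real oligomers requires
real force-field trajectories and is out of scope.

`rmsd_ca()` superposes matched C-alpha sets by the optimal
least-squares (Kabsch) rotation before computing the RMSD; with
`fit = FALSE` it is the direct RMSD, and fitted never exceeds unfitted.

# Domain partition

The head / hairpin / connector split is a required input
(`domain_partition()` of the shipped fixture provides one); for real
structures the residue ranges must come from the structure's
annotation, since no universal rule recovers them from coordinates.

# Problem sizes and numerical tolerances

The test-suite and worked-example sizes are chosen so the whole
distribution-recovery exercise is statistically meaningful at desk
scale: 150 rings for the diameter distribution (3 standard errors of
the configured SD 2.2 nm is ±0.54 nm), 100 arcs for height recovery
(tolerance 0.1 nm against a measured per-particle sd of ≈0.03 nm),
100 seeds per stoichiometry for the SNR-3 detection rate, and
19 stoichiometries for the exhaustive noiseless sweep. Scenes are
rendered at 0.5 nm/px (96–128 px fields). Interpolation tolerances
(0.06–0.08 nm for symmetrization idempotence, 1e-6 relative for exact
identities) reflect measured bicubic/bilinear error on the generator's
scenes; oracle equivalences (power spectra vs direct DFT sums, tip
dilation vs the sphere-touch contact model, counters vs all-pairs
enumeration) hold to 1e-10 or exactly.

# Known limitations

* The drift model is a global y-stretch; shear or time-varying drift
  is out of scope (and not quantitatively invertible anyway).
* ROI proposals come from ground truth or simple local-maximum
  seeding; there is no detector tuned for real-instrument artifacts.
* The alignment search is a dense grid with local refinement, adequate
  for the package's image sizes; it is not an FFT-accelerated
  correlator.
* The slit builder is rigid geometry; it does not relax junction
  clashes.
* Absolute surrogate-energy radii and fixture interaction counts are
  illustrative, not predictions about any real protein.
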