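---
title: "Simulating and quantifying gastruloid elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying gastruloid elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Gastruloids — aggregates of mouse embryonic stem cells — elongate over the
last day of their differentiation into a striking variety of shapes.
`gastruloidCPM` provides a two-dimensional Cellular Potts
(Glazier–Graner–Hogeweg) simulator of this process together with the
quantification pipeline needed to compare simulated and measured tissues:
LOCO-EFA lobe spectra, a two-dimensional Kolmogorov–Smirnov test, image
segmentation, and trajectory analysis. This vignette explains the model, the
numerical choices behind the implementation, and what the synthetic data used
by the test suite does and does not show about real tissues.

## The Cellular Potts model

Cells are sets of lattice sites sharing a spin $\sigma(\vec x)$ on a 2D
lattice; spin 0 is the surrounding medium. Dynamics are Metropolis-accepted
spin copies between Moore-adjacent (8-neighbor) sites, with acceptance
probability $1$ for $\Delta H \le 0$ and $e^{-\Delta H/T}$ otherwise; the
temperature $T$ sets cell motility. The energy is

$$H=\sum_{(\vec x,\vec x')}J\big(\tau(\sigma(\vec x)),\tau(\sigma(\vec x'))\big)
  \,(1-\delta_{\sigma(\vec x),\sigma(\vec x')})
  +\sum_{s}\Big[\lambda_1\,(A(s)-A_T)^2+\lambda_2\,(L(s)-L_T)^2\Big],$$

with interfacial energies $J$ per unit boundary length, an area constraint
toward $A_T$ and a length constraint toward $L_T$. Surface tensions derive
from $J$ as $\gamma(\tau,\tau') = J(\tau,\tau') -
\tfrac12\left(J(\tau,\tau)+J(\tau',\tau')\right)$ and
$\gamma(c,M)=J(c,M)-J(c,c)/2$; positive $\gamma(c,M)$ keeps the aggregate
compact, and the sign of $\gamma(1,2)$ decides whether two cell types sort or
mix.

Defaults (`cpm_params()`): $T=50$, $A_T=100$, $L_T=10$,
$\lambda_1=\lambda_2=5$, $J(c,M)=J(c,c)=10$, 200 cells, 100,000 Monte Carlo
steps (MCS). With $A_T = 100$ a disc-shaped cell has diameter
$\approx 11$ sites, so $L_T = 10$ keeps cells close to round.

**Cell length.** The length $L(s)$ entering the constraint is not pinned down
by the model description; we define it from the covariance matrix of the
cell's site coordinates as $L = 4\sqrt{\lambda_\max}$, which equals the
diameter for a filled disc (for a thin rod it reads about 15% above the
end-to-end extent — a deliberate trade-off: this moment-based form is the only
definition that can be maintained incrementally in $O(1)$ per copy). All
moment sums are integer-valued in double precision, so the incremental
bookkeeping is bit-exact; the test suite verifies it against from-scratch
recomputation after fuzzed runs.

**Boundary handling.** The lattice carries a one-site frame that is excluded
from all neighborhoods: frame sites are never copy targets or sources and
adhesion across the frame does not count. Tissues are given enough room
(default 400×400 for 200 cells) that contact with the frame is rare; a
warning is raised if it happens. There is no periodic wrap.

**Initialization.** The aggregate starts as a compact disc: cell nuclei are
scattered on a central disc of radius $\approx 1.06\sqrt{N A_T/\pi}$
(≈85 sites for the default 200 cells) and every disc site joins its nearest
nucleus, so cells begin connected and near target area. A short burn-in (100
MCS with the area and adhesion terms only) relaxes the Voronoi boundaries
before the production run. Cell connectivity is *not* enforced afterwards;
at strong pulling the tissue occasionally sheds single-cell satellites, and
the shape analysis deliberately scores the largest connected body.

**Cell death.** A cell whose area reaches zero is retired: its filopodia are
removed and its spin can never reappear. Its constraint terms remain in $H$
as constants, so removal is energetically penalized rather than silently
rewarded.

## The edge-list sampler

Only copies across cell boundaries can change the configuration, so the
sampler tracks the set $E$ of directed site pairs with unequal spins in two
mutually indexing arrays: `edgelist` maps the flattened (site,
neighbor-slot) index to an edge number, and the first $|E|$ entries of
`edgeindices` map edge numbers back to slots. A proposal is one uniform draw
from the dense prefix of `edgeindices`; after an accepted copy only the
changed site's neighborhood is revisited, and a removed edge is overwritten
by the edge from the last index, so the prefix never fragments and no
periodic defragmentation is needed. One MCS is $\lceil |E|/8\rceil$
attempts, with $|E|$ re-read as it changes — the rate at which a
conventional $|\Lambda|$-attempts-per-MCS sampler would hit boundary pairs.
The test suite checks the paired-array bijection after every fuzzed update,
compares the edge set against an exhaustive scan, and verifies that the
edge-list and conventional samplers produce statistically indistinguishable
cell-area distributions on a small system.

## Convergent extension by filopodial tension

Crawling-driven convergent extension is modeled as transient center-to-center
links. Each cell carries a polarization angle $P(s)$ (initially uniform on
$[0,2\pi)$) and, every `t_interval` = 20 MCS, draws up to $n_\max=3$ targets
uniformly among the cells whose centers lie within $r_\max = 2$ target
lengths *and* within a double cone of half-angle $\theta_\max = 45^\circ$
around $\pm P(s)$. Links add a work term to every proposed copy,

$$\Delta H_{\text{total}} = \Delta H + \lambda_F\sum_i (R_{i,\text{after}} -
R_{i,\text{before}}),$$

so copies that shorten links are favored — the tissue contracts along the
local polarization axis and extends perpendicular to it. Only links touching
the two affected cells contribute (all others cancel exactly); each link's
current length is cached and updated on accepted copies.

At every refresh the polarization performs a noise-free Vicsek update with
memory: $P_{\text{new}} = \arg(w\,e^{iP} + (1-w)\,e^{iP_{\text{avg}}})$ with
$P_{\text{avg}}$ the circular mean of the *linked* cells' polarizations and
$w = 0.99$. All cells update synchronously from the pre-refresh angles; a
zero-magnitude circular sum (antipodal tie) keeps the previous direction.
The location-based alternative (`repolarization_mode = "belmonte"`) points
$P_{\text{avg}}$ at the mean direction of the linked cells' centers instead;
it reproduces the behavior of the original filopodial-tension model that
assumed an externally imposed axis, and is included for comparison only.

Two-cell-type variants restrict who may link to whom (`same_type`,
`all_all`, `yellow_all`, `yellow_yellow`, types 1 = red, 2 = yellow, default
mosaic 50/50 — the mosaic fraction is not biologically pinned and is
configurable). The differential-adhesion model instead uses 10 presorted
cell types with $J(\tau,\tau') = O + |\tau-\tau'|\,S$, $J(\tau,M)=25$, no
pulling, and 120,000 MCS; the bands are laid along the x-axis (arbitrary by
isotropy).

## Shape quantification: LOCO-EFA

Tissue outlines are traced from the binary mask (all cells vs medium) with a
marching-squares 0.5-level contour. The mask is first smoothed with a
1-site Gaussian so the level set interpolates sub-site positions instead of
following the staircase of the lattice; this removes a ~4% perimeter bias
on discs and has negligible effect on modes 2–3. Elliptic Fourier analysis
(Kuhl–Giardina) of the arc-length parameterized outline gives per-harmonic
coefficient matrices; each is split into two counter-rotating circular
phasors $\lambda^+_n e^{i(nt+\zeta^+_n)}$ and $\lambda^-_n
e^{i(-nt+\zeta^-_n)}$. Relative to the base traversal, a prograde phasor of
harmonic $l+1$ and a retrograde phasor of harmonic $l-1$ both modulate the
outline with $l$ lobes, so the $l$-lobe amplitude combines them with their
phase interference:

$$L_l=\sqrt{(\lambda^+_{l+1})^2+(\lambda^-_{l-1})^2+
  2\lambda^+_{l+1}\lambda^-_{l-1}\cos(\zeta^+_{l+1}+\zeta^-_{l-1}-2\zeta^+_1)},
  \qquad L_1=\lambda^+_1 .$$

This construction makes $L_1$ the base-circle radius (a measure of linear
size) and reproduces $r(\theta)=R(1+a\cos l\theta)$ flowers with $L_l
\approx aR$ exactly; the combination is invariant under rotation,
translation, scaling (after division by $L_1$), and start-point shifts —
each verified to $10^{-6}$ on fuzzed shapes. Analyses use the scaled
coefficients $L_2/L_1$ and $L_3/L_1$ only: higher modes are increasingly
contaminated by lattice noise, which the suite demonstrates by comparing
continuous contours with their rasterized masks (modes 2–3 agree within 5%,
higher modes need not).

## Distribution comparison

Two clouds of $(L_2/L_1, L_3/L_1)$ points are compared with the
Fasano–Franceschini two-dimensional Kolmogorov–Smirnov statistic: around
every data point of each sample the plane is split into four open quadrants
(points on a dividing line, including the origin itself, are excluded — a
convention fixed by a brute-force oracle test), and $D$ is the maximum
quadrant-fraction difference, averaged over the two sample-origin passes.
$D=0$ for identical samples and $D=1$ for clouds confined to opposite
quadrants. The asymptotic p-value uses the 1D KS tail with effective size
$n_1n_2/(n_1+n_2)$ and the Press-style correlation correction
$\sqrt{1-\tfrac12(r_1^2+r_2^2)}$; it is approximate at small $n$, so a
label-permutation p-value (seeded, $+1$-corrected) is provided and preferred.
Variance comparisons between conditions use the Brown–Forsythe test:
absolute deviations from the group medians, then a one-way ANOVA F-test.

## Segmentation and trajectories

The wide-field segmentation pipeline is fixed-parameter and deterministic:
Gaussian blur ($\sigma=5$ px) → Otsu threshold on the blurred image →
dilation then opening (disc radius 10) → Euclidean distance transform →
plateau-centroid local maxima with ≥70 px separation as markers → Scharr
gradient magnitude as elevation → marker-based watershed (Meyer
priority-flood, with the image border as background marker) → objects under
1000 px or within 2 px of the border dropped. Time-lapse frames become a
single tissue mask by blur + fixed threshold + 40 iterations of 5×5 dilation
then erosion (4 iterations of erosion-then-dilation for already-binary
simulated frames).

Tracked positions are mapped into the tissue frame by fitting an ellipse
(direct least-squares conic fit) to each frame's mask, subtracting its
center, and rotating by $-\theta$; the reported $\theta$ of near-circular
fits is unreliable and flagged (axis ratio < 1.05), and the $\pi/2$
ambiguity of ellipse orientation is resolved per frame against the previous
frame. Net movements are normalized by the final long/short axis lengths;
simulated tracks start at 20,000 MCS because the elongation axis is not yet
defined earlier. Relative positions of points inside a mask are projections
on the mask's principal axes, min-max scaled to its extent.

## Synthetic data and what the tests show

All tests run on generated data: soft-edged discs plus Gaussian noise
(16-bit, emulating denoised wide-field images), analytic shape families with
known lobe structure (circle, ellipse, $n$-flowers, snowman as two
overlapping discs), and tracks advected by an incompressible stretch flow
$(x,y)\to(k_tx, y/k_t)$ with optional rigid motion — a closed-form
convergent-extension stand-in. These fixtures pin the *code*: geometry,
invariances, statistical calibration, and pipeline determinism. They do not
emulate uneven illumination, debris, out-of-focus light, 3D projection
effects, or cell division, so passing tests validate the algorithms rather
than promise segmentation accuracy on any particular microscope's output.

## Problem sizes used by the checks

Monte Carlo studies in the test suite and the acceptance script are run at
reduced repeat counts, and — where the check is qualitative — on smaller
tissues (60–100 cells, 30,000–40,000 MCS) chosen so each condition completes
in minutes on one core while leaving the study conditions of the headline
checks (200 cells, $\lambda_F=20$, $\gamma(c,M)=15$, 100,000 MCS) intact.
Fractions of runs in the circular or elongated phase are judged against
3-sigma binomial bands at the reduced repeat count. Two caveats follow. First,
small tissues elongate earlier (fewer cells must align), so phase-timing
statistics are only meaningful at full scale. Second, with single-digit
repeats the bands are wide; the acceptance script reports the raw fractions
alongside the counts so the uncertainty is visible.

A further honesty note: in this implementation the elongation onset at full
scale is less sharply synchronized across runs than the published phase
counts suggest — some runs elongate before 50,000 MCS and elongated tissues
occasionally relax back toward circular within the run. The ingredients
(energy terms, sampler, polarization dynamics, parameters) follow the stated
model; the phase timing is sensitive to implementation details the model
statement does not pin down (cell-length definition, initialization,
refresh bookkeeping), and the phase-count checks should be read with that
sensitivity in mind.

## Reproducibility

Every stochastic component is seeded: a run's seed fixes the blob layout,
type assignment, polarization initialization, filopodia draws and the copy
chain (the proposal stream and the filopodia stream are independent, so a
$\lambda_F=0$ run is bit-identical to a run without the filopodia machinery
at the same seed). Repeats derive seeds as `seed + repeat index`.
`run_experiment()` writes a manifest (config snapshot, seeds, package
version) next to its outputs, and equal config + seed reproduces outputs
bitwise.
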