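---
title: "Statistical mechanics of DNA origami hinge force spectrometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical mechanics of DNA origami hinge force spectrometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingeforce)
```

## The measurement and the model

A nanoscale DNA force spectrometer (nDFS) is a DNA origami hinge: two stiff
~61 nm arms joined at a vertex whose single-stranded connections set the
angular stiffness. Electron micrographs of deposited particles yield one
interior hinge angle $\theta$ per particle. Because the particles
equilibrate before deposition, the angle histogram is treated as a
Boltzmann-weighted conformational ensemble, so

$$G(\theta) = -k_BT \ln p(\theta) + \text{const},$$

which is the whole basis of the landscape module: a histogram density (5°
bins by default, bin centers anchored at multiples of the width), a
free-energy landscape on the bins whose density exceeds a cutoff (0.001 per
degree by default — below that too few particles were observed for $-\ln p$
to be meaningful), minimum shifted to zero, and a cubic smoothing spline
through the retained points. Torque is the angular derivative of the
smoothed landscape ($\tau = -dG/d\theta$, $\theta$ in radians, scaled by
$k_BT$ to pN·nm), and the force available at radial position $d$ along an
arm is $\tau/d$; the default radial range 11–61 nm starts at the 32-bp
crossover repeat of the square-lattice bundle. All uncertainties come from
case resampling: $N$-from-$N$ bootstrap with 50 replicates by default.

Sample-size guidance follows the convergence behaviour of these landscapes:
below roughly 150 particles the histogram-derived landscape is not stable,
so `estimate_density()` warns there.

## Polymer models

The dsDNA sample spanning the arm tips (249 bp, i.e. 84.66 nm at
0.34 nm/bp) is a worm-like chain with persistence length 50 nm. Because
$l_p/L_c \approx 0.6$ is not small, the end-to-end distance density uses
the stiff-polymer closed form: a scaling function of
$x = (l_p/L_c)(1 - R/L_c)$ with two three-term series branches switched at
$x = 0.2$ (the branches agree to ~0.04% there). The normalization over
$(0, L_c)$ is computed once per parameter set by adaptive quadrature and
cached. The density is one-dimensional in the scalar distance — no $R^2$
Jacobian — which is exactly how it enters the coupling integral below.

Free energy and force follow by Boltzmann inversion of this density:
$G(R) = -k_BT\ln p(R)$ referenced to the density mode, and
$F = -dG/dR$ by a centered finite difference (0.1 nm half-step by
default; the truncation error at that step is far below the measurement
bands of interest). Deep in compression the first series term dominates, so
$G$ is asymptotically linear in $R$ with slope $-k_BT\pi^2 l_p/L_c^2$ and
the force plateaus at $\pi^2 l_p k_BT/L_c^2 \approx 0.28$ pN — the number
the compression experiment is compared against.

The short flexible linkages holding the sample (two 6-nt overhangs, two
biotins and a neutravidin, lumped) are Gaussian chains with density
$p(R_p) = (3/2\pi nb^2)^{3/2}\exp(-3R_p^2/2nb^2)$. The defaults $n = 4$,
$b = 1.5$ nm (RMS end-to-end distance 3 nm, about the physical size of the
lumped linkage) are an explicit assumption: nothing in the angle data pins
them down, so they are exposed in the configuration and varied in tests
only through their closed-form consequences.

Thermal energy defaults to $k_BT = 4.114$ pN·nm (298 K); it is a parameter
everywhere, never a hard-coded constant inside a formula.

## The coupling integral

With a sample incorporated, each hinge angle $\theta$ fixes the tip-to-tip
chord $2L\sin(\theta/2)$ (82 nm at the 85° peak of the open device). The
predicted angle distribution reweights the free-device prior by the
configurational weight of linker1 + sample + linker2 closing that chord:

$$P(\theta) \propto p_{\text{free}}(\theta)\sum_{\mathbf R_{p1},\mathbf
R_{p2}} p(R_{p1})\,p(R_{p2})\,p_{\text{WLC}}(|\,\mathbf c(\theta) -
\mathbf R_{p1} - \mathbf R_{p2}|)\,\mathrm dV_1\,\mathrm dV_2 .$$

The linker vectors are enumerated on a spherical grid of spacing
$\Delta R = 2$ nm with per-shell angular spacings $\Delta\vartheta =
\Delta R/R$ and $\Delta\varphi = \Delta R/(R\sin\vartheta)$, radial support
$(0, nb)$; the cells are then approximately cubes, and the quadrature
weight carries the $R^2\sin\vartheta$ measure. The sample vector is never
gridded: it is computed exactly from vector closure against the chord, and
its density is evaluated at that distance (zero at or beyond $L_c$), which
avoids any double-discretization of the closure constraint. Halving
$\Delta R$ moves the prediction by under 0.1% total variation at the
default parameter set, so 2 nm is comfortably converged.

A 6-D-to-5-D reduction via the azimuthal symmetry of one linker was
considered and rejected: the full enumeration is a single vectorized outer
product over precomputed point sets and runs in tens of milliseconds, so
the symmetry trick would buy nothing while complicating the bit-level
correspondence with the naive sum. The independent cross-check is instead a
separate importance-weighted Monte-Carlo sampler (`sample_coupled_mc()`)
that draws linker vectors from the actual 3-D Gaussian (rejecting the
negligible mass beyond the $nb$ support limit so both routes integrate the
same model) — the two agree to total-variation distance below 0.01 at
$2\times10^5$ samples.

The force on the sample converts the angular slope through the chord rule
$dr/d\theta = L\cos(\theta/2)$: $F = -(dG/d\theta)/(dr/d\theta)$. We keep
the sign convention of the single-polymer module: positive values are the
compressive load borne by the sample below its preferred extension,
negative values tension. With a flat hinge prior and point linkers the
whole construction collapses, as it must, onto the single-polymer WLC force
at the chord distance (it does, to under 1% away from bin edges).

## Nucleosome unwrapping

A nucleosome on the construct wraps 147 bp over 1.67 superhelical turns
(radius 4.18 nm, pitch 2.39 nm — canonical crystal-structure values, all
configurable), leaving 51 bp of straight linker per side. An unwrapping
state releases $n_1$ and $n_2$ bp from the two ends; the released DNA plus
linker extends along the line tangent to the wrap at the last point of
contact, and the distance between the two free ends is inverted through the
chord relation to the hinge angle $\theta(n_1, n_2)$.

Two geometric backends are provided: `"planar"` (default) projects the
superhelix to a circle; `"helix"` keeps the 3-D pitch. They differ by
about 2° at the fully wrapped state, which is below every other uncertainty
in the problem, and the planar map is easier to reason about. One genuine
feature deserves emphasis: because the wrap exceeds a full turn, the exit
tangents rotate through more than 360° as unwrapping proceeds, so
$\theta(n_1, n_2)$ *oscillates* over the first turn — the familiar
spool-unwinding geometry. It becomes monotone only for sub-single-turn toy
constructs, which is where the monotonicity property is asserted in the
test suite.

The unwrapping prediction is the exhaustive partition-function sum: every
state is weighted by $P_{\theta(n_1,n_2)}e^{-\varepsilon(n_1,n_2)/k_BT}$,
where $P_\theta$ is the free-device probability mass at the angle bin the
state maps into, states are sorted into 3-bp bins of total unwrapped bp,
and the binned weights are normalized by $wZ$. The same joint weight
marginalized over angle bins gives the constrained device distribution.
Adding any constant to every state energy cancels in $Z$ (there is an
explicit gauge parameter to demonstrate it). With a flat device prior the
prior cancels and the result is the pure Boltzmann sum of the energy model;
with flat energies the constrained angle distribution is the prior
reweighted by the per-bin state multiplicity — multiplicity does not cancel,
because many $(n_1, n_2)$ states can share one angle bin.

The energy model is the deliberately simple part. The original unwrapping
energies for this construct come from an external nucleosome model that is
out of scope here, so the default is a transparent two-level per-bp net
adhesion: 0.15 $k_BT$/bp over the outer 39 bp from each end, 1.0 $k_BT$/bp
inside — outer-turn unwrapping thermally accessible, inner turn strongly
held, consistent with the scale at which spontaneous unwrapping is
observed. Absolute unwrapping totals are therefore calibration-dependent
and only *orderings* across device variants are treated as conclusions:
open-biased devices (nDFS.B-like) must and do induce more unwrapping than
closed-biased ones (nDFS.C-35-like), which in turn exceed the free
nucleosome's thermal unwrapping.

Tensile forces on the nucleosome are read off the free-device landscape at
the constrained most-likely angle $\theta^*$ (spline mode by default):
$F = -(dG/d\theta)/(L\cos(\theta^*/2))$, positive when the device slopes
toward opening, i.e. pulls on the sample. The alternative torque-over-radius
estimate is attached as an attribute so the two conventions can be compared;
they differ by the factor $\cos(\theta^*/2)$.

## Elastica mechanics

The strongly bent dsDNA in the toggled-closed device resembles a
post-buckled slender beam, so the package also solves the Euler elastica
with bending rigidity $EI = l_p k_BT$. Ends are pinned-pinned by default —
the biotin–neutravidin linkages rotate freely — with clamped-clamped as an
option. The end-to-end distance fixes the elliptic modulus through
$e/L_c = 2E(k)/K(k) - 1$ and the force is $F = 4K(k)^2EI/L_c^2$
(quadrupled for clamped ends), root-found to $10^{-12}$ in the parameter
$m = k^2$. The branch joins the critical load $\pi^2EI/L_c^2$ continuously
as $e \to L_c$. At the experimentally bent state (49 nm end-to-end, i.e.
36 nm of shortening) this gives ~0.36 pN against the WLC plateau's
~0.28 pN; the two models agree at the tens-of-percent level across the
compressed range, which is as much agreement as two such different
idealizations support.

## Synthetic data

No deposited angle tables exist, so the generator emulates them. Each
device variant is a skew-normal truncated to (0°, 180°) plus 2° of Gaussian
measurement noise (a stand-in for manual two-line angle picking; no error
model was reported, and 2° is a conservative reading precision). Parameters
were fixed once from the reported summary statistics: nDFS.A location 70°,
scale 14°, no skew; nDFS.B location 83°, scale 12°, no skew (mean 83°,
~97% of mass above 60°); nDFS.C-35 location 25°, scale 19°, shape 4, whose
half-normal-like right tail puts ~93% of mass below 60°. What the generator
does *not* emulate: 2-D projection bias of deposited 3-D conformations,
surface-interaction distortions, or particle-picking selection effects — so
passing round-trip tests demonstrates the correctness of the inversion
machinery, not the absence of instrument bias in real data.

All generators are pure functions of (parameters, seed); the fixture suite
writes CSVs plus a JSON manifest of every seed and regenerates
byte-identically.

## Numerical choices and problem sizes

- Quadrature: `stats::integrate` at `rel.tol = 1e-10` for normalizations
  and moments; cached per spec.
- Derivatives: centered finite differences (0.1 nm in distance, 0.1° in
  angle) on smoothed curves; spline smoothing by generalized
  cross-validation unless `spar` is supplied.
- Root finding: `uniroot` on the elliptic modulus, bracketed in
  $(10^{-300}, 1-10^{-12})$.
- Degenerate inputs: point linkers (chains whose full extent falls below
  half a grid cell) collapse to a single origin point; angles at or beyond
  the contour-length closure get zero density rather than errors; all-zero
  predictions abort with a model error.
- Test and example problem sizes were chosen so the full suite runs in
  seconds: ensembles of 150–500 angles (matching the reported per-device
  sample sizes), $2\times10^5$-draw Monte-Carlo oracles, a 30-bp toy
  nucleosome for exhaustive enumeration, and $10^4$ end-to-end samples in
  the reproduction script.

## Worked example

```{r example, eval = FALSE}
ens <- generate_angle_ensemble(device_variant("nDFS.B"), N = 500, seed = 7)
dist <- estimate_density(ens, bin_width = 5)
fel <- boltzmann_free_energy(dist)
tq <- torque_profile(fel)
fm <- force_map(tq)

lk <- gaussian_chain(4, 1.5)
spec <- coupled_system(dist, lk, lk, wlc(85, 50))
pred <- predict_coupled_angle_distribution(spec)

uw <- predict_unwrap_distribution(dist, nucleosome_spec(), hinge_geometry())
mean_unwrapped(uw)
```

## Known limitations

- The stiff-polymer density is invalid for $l_p \ll L_c$; the constructor
  warns below $l_p/L_c = 0.1$.
- Measured angles are taken at face value as the conformational coordinate;
  projection and deposition biases are upstream of this package.
- Absolute nucleosome unwrapping numbers inherit the adhesion calibration;
  treat them as model output under a stated energy model, not as
  measurements.
- Arm-end fraying, H2A–H2B dimer loss and other local deformations invoked
  qualitatively for residual discrepancies are not modeled.
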