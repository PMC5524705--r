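---
title: "Quantitative cryo-ptychographic tomography: models, conventions and validation"
author: "cryoPXCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cryo-ptychographic tomography: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and its model

Ptychographic X-ray computed tomography (PXCT) images thick, unstained,
frozen-hydrated specimens by combining two inversions. At each tomographic
angle, a confined coherent beam (the *probe*) is scanned across the sample
in overlapping spots while a far-field detector records one diffraction
pattern per spot; iterative phase retrieval recovers the complex-valued
transmission of the sample at that angle. The phase images of all angles
are then aligned and fed to filtered back-projection, producing a 3-D map
of the refractive-index decrement $\delta$ that calibrates directly to
electron density, and through a composition assumption, to mass density.

`cryoPXCT` implements this chain end to end at desk scale, with a
synthetic tissue phantom and a diffraction simulator standing in for the
beamline. Because the phantom's electron density is known voxel by voxel,
every stage — phase retrieval, alignment, reconstruction, calibration,
resolution and dose estimation — can be validated against ground truth.

### Physical model and conventions

All conventions below are fixed package-wide.

* **Grids** are indexed $(y, x, z)$ with $y$ the vertical rotation axis and
  the beam along $+z$ at $0°$; the system is right-handed; angles are in
  degrees on $[0°, 180°)$.
* **Refractive index** $n = 1 - \delta + i\beta$. A projection under the
  multiplicative (projection) approximation is
  $T = \exp\!\big(-\tfrac{2\pi}{\lambda}\textstyle\int \beta\,dz\big)\,
       \exp\!\big(-i\tfrac{2\pi}{\lambda}\textstyle\int \delta\,dz\big)$,
  so denser material has **more negative phase** and $|T| \le 1$.
* **Electron density.** $\delta = r_e \lambda^2 n_e / 2\pi$ with $r_e$ the
  classical electron radius; inverted exactly after reconstruction. Mass
  density uses $\rho_m = n_e \cdot 1.86\,\mathrm{g/mol} / N_A$, the molar
  mass per electron of hydrated biological material (water/lipid/protein/
  chromatin); for pure water the true ratio is 1.80 g/mol, so the
  conversion is a few percent high on water — within the stated certainty
  of the composition assumption.
* **DFT scaling** is orthonormal everywhere, so Parseval's identity holds
  without bookkeeping factors and simulated detector counts never exceed
  the photon budget.
* **Sub-pixel shifts** are Fourier phase ramps; shifts of projections are
  applied after 10% edge-replication padding to suppress periodic
  wrap-around.

### The synthetic phantom

`phantomSpec()` describes a vitrified tissue block strictly inside a
cylindrical support, surrounded by air on all sides of the rotation axis
— the condition that anchors absolute phase and avoids a missing wedge.
Its feature classes emulate sucrose/PVP-infused brain tissue: medium
(cryoprotectant, 0.40 e/Å³), cytoplasm (0.37) with internal nucleus
ellipsoids (0.35), vertical myelinated axons (annular sheath 0.34 around
axoplasm 0.36), and ~3 µm pigmented vacuoles (lipid 0.31 with a dense
pigment sub-sphere 0.45). The field-reported observations these defaults
encode are *orderings*: myelin below the surrounding medium, vacuole lipid
below both, nucleus below cytoplasm. The absolute values are this
package's choices (the source imaging reports orderings, not per-class
numbers) and every one is overridable.

Two generator choices deserve comment:

* **Sheath thickness.** Default sheaths are 1.0–1.4 µm, thicker than most
  real myelin, so that a 2-voxel interior erosion at the 200 nm desk voxel
  still leaves sheath-interior voxels to quantify. Thin sheaths at this
  voxel size would be pure partial-volume objects for *any* method.
* **Overlap precedence.** Overlapping features resolve by precedence
  (pigment > vacuole > nucleus > myelin > axoplasm > cytoplasm > medium),
  painted in increasing order; they are never an error.

What the generator does **not** emulate: real anatomical texture and
membrane-scale detail, grazing-incidence edge reflections (corrupted
projections are instead *injected* when testing their detector),
wavefront defects, detector gaps and read noise, partial coherence.
Passing tests therefore demonstrate the correctness of the inversion
chain, not robustness to every beamline nonideality.

### Forward model

The scan follows a Fermat spiral ($r = c\sqrt{k}$, golden-angle azimuth,
$c = \mathrm{step}/\sqrt{\pi}$ so the mean area per point is step²),
clipped to the field of view — near-uniform density without raster
artifacts. The probe is a tapered disc (raised-cosine edge, width 10% of
the diameter) with a quadratic defocus phase, normalized to the photon
budget; only its extent and overlap matter here, since reconstruction
retrieves the probe jointly with the object. The photon budget per
exposure is fluence × scanned area / number of positions, so the stated
fluence per projection includes the overlap. Detector statistics are pure
Poisson.

In the pipeline profiles, scan positions are snapped to the
reconstruction pixel grid at generation time. Continuous positions and
exact Fourier-shift sub-pixel probe placement are implemented and tested
in both the simulator and the solver, but grid-snapped scans make the
difference-map inner loop considerably cheaper (no per-position shift
transforms), and at the profile step sizes the snap moves positions by
at most half a pixel — irrelevant to every conclusion the profiles are
used for.

### Phase retrieval

`dmReconstruct()` is the classic difference map on per-position exit
waves $\psi_j$: $\psi \leftarrow \psi + P_F(2P_O(\psi) - \psi) -
P_O(\psi)$, with the overlap projection computing the least-squares
object and probe from the current exit waves, and the Fourier projection
replacing modeled amplitudes with measured $\sqrt{I}$. Numerical
choices: the overlap denominators are *floored* at $10^{-8}\times$ their
maximum (an additive regulariser would bias the exact fixed point — with
the floor, exact data are reproduced to machine precision); the probe is
frozen for the first 10 iterations; relaxation is the classic $\beta = 1$
map; Fourier-domain pixels whose modeled amplitude is zero keep their
value (no free pixels). The per-iteration Fourier error
$\sqrt{\sum(|\Psi| - \sqrt{I})^2 / \sum I}$ is recorded.

`mlRefine()` polishes the difference-map solution by minimizing the
Poisson negative log-likelihood with a preconditioned (illumination- and
object-power) Polak–Ribière conjugate gradient, analytic Wirtinger
gradients, and a parabolic line search that only ever accepts decreasing
steps; a failed line search returns the current state with a flag rather
than an error. The likelihood regulariser is $10^{-8}\max(I)$ inside the
logarithm; doubling it moves the final objective by well under 0.1%.

A reconstruction is determined only up to a global phase offset and a
linear phase ramp. `removePhaseAmbiguity()` estimates both wrap-safely
from $\mathrm{rec}\cdot\overline{\mathrm{ref}}$; all comparisons to
ground truth go through it. In the pipeline the air region serves the
same role absolutely: fitting and subtracting a plane over air
(`removeRamp`) anchors every projection's phase to vacuum.

### Alignment

Processing is derivative-domain throughout: the wrap-safe horizontal
difference $d = \mathrm{Arg}(T_{x+1}\overline{T_x})$ tolerates total
phases far beyond $2\pi$ (only a *per-pixel* step above $\pi$ wraps; a
step of exactly $2\pi$ is invisible — a documented limitation shared with
the derivative formulation itself).

* **Vertical.** The vertically integrated projected mass per slice is
  rotation-invariant, so the per-angle profiles $m_\theta(y) = \sum_x
  \phi_\theta(x,y)$ (with $\phi$ integrated from the derivative — the raw
  derivative telescopes to zero across a row) must agree up to shifts.
  Shifts are estimated against the running mean profile with sub-pixel
  cross-correlation, iterated, zero-mean gauge.
* **Horizontal.** A centre-of-mass fit to $A\cos(\theta + \phi_0) + c$
  initializes; tomographic consistency refines: reconstruct a central
  slab, reproject at every angle, register each projection to its
  reprojection by upsampled cross-correlation (0.01 px quantization),
  iterate to a 0.05 px tolerance with a divergence guard.
* **Identifiability.** A shift field of the form $A\cos\theta +
  B\sin\theta + C$ is *tomographically consistent* — it corresponds to a
  rigid translation of the object and cannot be observed from projection
  data. Alignment accuracy is therefore assessed modulo this
  three-dimensional subspace; the unobservable component merely
  translates the tomogram by a sub-pixel amount.
* **Rejection.** Projections with localized transmissivity loss are
  flagged automatically: the minimum 5×5 boxcar mean amplitude inside the
  (eroded) support, thresholded at 5 scaled MADs below the across-angle
  median, with a manual override list in the configuration. Retained
  angles are weighted by their angular gaps (periodic over 180°,
  normalized to sum to the angle count).

### Reconstruction

`derivativeFBP()` reconstructs slice by slice (exact under the
parallel-beam assumption). The continuum filter for phase-derivative
projections is $-(i/2\pi)\,\mathrm{sign}(w)$ — the ramp $|w|$ divided by
the transfer function of differentiation. Discretely, three choices
matter and were validated against an area-averaged analytic disc:

1. the ramp is realized from the band-limited spatial kernel (¼ at lag 0,
   $-1/\pi^2 n^2$ at odd lags) and divided by the exact forward-difference
   transfer function $e^{i2\pi w} - 1$, which removes the ~5% cupping of a
   naively sampled $|w|$;
2. the ramp's DC bin, which derivative data cannot carry, is restored
   explicitly from the integrated projection;
3. projections are zero-padded to 4× width, and back-projection samples
   the *full padded* filtered projection periodically — the filter's
   slowly decaying tails are needed for cancellation outside the sample.

With these choices the analytic-disc interior is recovered to ~0.4%
(worst case < 2%) and the air region to a mean of ~0.7% of the interior
value. Pointwise air error directly at the 3-voxel exclusion band is
Gibbs ringing of the band-limited ramp, common to all FBP
implementations. The volume in phase-per-voxel units converts to
$\delta = -v\lambda/(2\pi\,\mathrm{voxel})$, positive in matter under the
sign convention above.

### Resolution, dose, segmentation

**FSC.** Half-tomograms from even/odd angle subsets (an angle-split; a
scan-split is the other common choice and the split is configurable in
the sense that any index partition can be reconstructed directly) are
correlated shell by shell after a shared separable Hann apodization, with
the half-bit information threshold
$T = (0.2071 + 1.9102/\sqrt{n})/(1.2071 + 0.9102/\sqrt{n})$ and linear
interpolation of the first crossing. Two caveats are deliberate: the
resolution is floored at two voxels (Nyquist), and the *null-level*
calibration of the statistic (independent noise decorrelating as
$1/\sqrt{n}$) is checked unwindowed, because apodization smooths the
spectrum and correlates within-shell samples, inflating the null variance
— windowing is a box-boundary measure for real reconstructions, not part
of the statistic's calibration.

**Dose.** Surface dose of a weakly absorbing medium:
$D = \Phi\,E\,\mu/\rho$ per projection with $\mu/\rho = 1/(\Lambda\rho)$;
water at 6.2 keV ($\Lambda = 451\,\mu m$, $\rho = 1000$ kg/m³) gives
22.0 kGy per projection at $10^7$ photons/µm², hence 9.8 / 19.7 / 17.3 MGy
for 446 / 894 / 785 projections — consistent with the reported 11 / 21 /
20 MGy at the stated "approximately" $10^7$ fluence (the printed inputs
alone cannot reproduce the printed doses exactly).

**Segmentation.** Density-band thresholding followed by 26-connectivity
components (via `igraph`), a minimum-size filter, and equivalent-sphere
diameters $(6V/\pi)^{1/3}$ per class. In the pipeline the bands sit at
midpoints between the class densities and segmentation is confined to the
eroded support interior — the partial-volume ring at the air boundary
sweeps through every band and would otherwise contaminate the counts.

**Depth of field.** $\mathrm{DOF} = 5.2\,r^2/\lambda$ advisory: at 6.2 keV
a 50 nm target resolution tolerates ~65 µm of thickness; the check flags
but never blocks.

### Study profiles and problem sizes

`deskProfile()` is the package's standard study: 6.2 keV optics scaled to
a 64-pixel detector region (200 nm pixels), a 128×128×64 phantom, a
31-pixel (6.2 µm) probe on a Fermat spiral with 3 µm steps (~42 positions
per angle, scanning 1.6 µm past the sample so the air margin used for
phase anchoring is properly illuminated), 60 angles, 150 difference-map +
30 maximum-likelihood iterations per angle. It runs in a few minutes on
one CPU and recovers every class's median electron density within 5%.
`beamlineGeometryProfile()` carries the full-scale beamline geometry (43.2 nm
pixels, 446–894 angles, 800/600 + 150/100 iterations) for geometry- and
dose-derived quantities; simulating at that scale is not the package's
purpose. The noisy mini-profiles used for the resolution-vs-photon-budget
check are 64×64×32 phantoms, 48 angles, 32-pixel frames at $10^3$–$10^4$
photons per frame.

### Known limitations

* Single probe mode, no position refinement, no multi-slice model: the
  projection approximation bounds validity to samples thinner than the
  depth of field at the target resolution.
* The phase derivative cannot see per-pixel steps above $\pi$; violently
  refractive edges alias (the motivation for cylindrical samples).
* Per-angle probe retrieval is independent; sharing the probe across
  angles is a possible refinement the architecture would permit.
* The mass-density conversion inherits the composition assumption behind
  1.86 g/mol; the package reports the conversion and does not re-derive
  its uncertainty bound.
* Automatic bad-projection flagging is a stated stand-in for what was a
  manual curation step in practice; the MAD rule is validated on injected
  corruptions only.

## Reproducing the numbers

`scripts/acceptance.R` recomputes every headline quantity from scratch —
geometry, doses, conversions, phase-retrieval and alignment accuracy, the
disc oracle, the desk end-to-end run and the noisy resolution pair — and
writes them to JSON; see the README for invocation.
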