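---
title: "Methods: dose model, bolus operators, intensity modulation and QA in imbect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose model, bolus operators, intensity modulation and QA in imbect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbect)
```

# Scope

`imbect` implements the planning-and-verification chain for
intensity-modulated bolus electron conformal therapy (IM-BECT):

1. a **beam model** for a matched clinical electron beam;
2. **synthetic phantoms** and apertures so the chain is testable without
   patient data;
3. a **pencil-beam dose engine** with island-block (tungsten pin) fluence
   modulation;
4. the **bolus design operators** (create, smooth, isodose shift, specified
   shift, truncate, height extension) and their sequencing;
5. derivation of the **intensity-reduction-factor (IRF) map** from ray-line
   maximum dose;
6. **segmentation** of the IRF map into a hexagonal island-block pattern
   with iterative refinement;
7. planar **quality assurance** (dose difference / distance-to-agreement)
   and **DVH plan metrics**.

Everything is expressed in the beam-eye coordinate system: the virtual
electron source at $z=0$, the collimator (modulator) plane at $z=93.5$ cm,
the isocenter plane at $z=100$ cm. Pencil beams are indexed by *fan lines* —
diverging rays from the source through a regular $(x_i, y_j)$ lattice in the
isocenter plane (default spacing 0.2 cm).

# Beam model

Commissioned accelerator data are not shipped; instead `make_beam(r90,
energy)` builds an analytic central-axis percent-depth-dose (PDD) family:

* parabolic buildup from the surface dose (default 85%) to 100% at
  $R_{100} = 0.6\,R_{90}$;
* a logistic falloff anchored exactly at $(R_{100}, 100)$ and $(R_{90},
  90)$, reaching the x-ray tail at the practical range $R_p = 0.5\,E$ cm
  ($E$ in MeV — both standard electron rules of thumb);
* a constant bremsstrahlung tail beyond $R_p$ (default 3% of the given dose
  for 16 MeV, configurable).

Only the anchor points and monotonicity are treated as physical claims; the
curve is a self-contained, desk-scale stand-in whose *internal consistency*
is what the tests exercise. The tabulated PDD is interpreted as the measured
central-axis curve at the reference SSD of 100 cm, i.e. divergence is already
inside it; the engine therefore applies inverse square *relative to the
reference geometry* (see below).

When an island-block intensity modulator is in the beam, two corrections are
applied (`apply_modulator_corrections()`): the depth-dose curve is rigidly
shifted 0.1 cm shallower (energy loss in the 1.27 cm machinable-foam carrier,
$\rho = 0.096\ \mathrm{g\,cm^{-3}}$ — the density is metadata only; the
transport is the rigid shift), and the initial angular spread
$\sigma_{\theta_0}$ is multiplied by exactly 1.5 (foam scatter). The
operation deliberately composes (twice = 0.2 cm and $\times 2.25$), so
callers check the `modulator_corrected` flag rather than re-applying.

The unmodulated $\sigma_{\theta_0}$ of a specific accelerator is not public
data; the package default is **0.035 rad**, chosen to give a realistic
in-air penumbra downstream of the 93.5 cm collimator. It is a prominent,
configurable default (`beam` block of the run config), not a commissioned
value.

# Dose engine

Dose is the sum of an electron and an x-ray background component,
$D = D_e + D_X$. Per transverse slice at depth $d$:

$$D_e(x,y) = \sum_{ij} w_{ij}\,\varphi_{ij}\,
  P_e(d_\mathrm{eff})\,\left(\tfrac{100+d_\mathrm{eff}}{z}\right)^2
  G_{\sigma(d)}(x - x_{ij}, y - y_{ij})$$

* $\varphi_{ij}$ is the **surface fluence**: the aperture indicator projected
  by similar triangles and spread by an in-air Gaussian
  $\sigma_\mathrm{air} = \sigma_\theta (z_\mathrm{surf} - z_\mathrm{col})$.
  Island blocks are subtracted in this first transport step only, each as a
  square pencil of side $d\sqrt{\pi}/2$ (equal area to the circular pin)
  spread by the same Gaussian and carried as *negative fluence*; negative
  sums (overlapping shadows) are clamped to zero. All electrons striking a
  pin's top face are removed — perfect collimation, no pin-side scatter, no
  bremsstrahlung perturbation.
* $w_{ij}$ are the per-line modulation weights (the IRF map; 1 for an
  unmodulated beam). They multiply both components, so dose is exactly
  linear in the weights — for the idealized modulated beam the fluence
  reduction applies upstream of bremsstrahlung production. Physical island
  blocks, by contrast, enter through $\varphi$ and leave $D_X$ untouched.
* $P_e$ is the electron part of the PDD (total minus the ramped x-ray
  background), evaluated at the water-equivalent depth $d_\mathrm{eff}$ —
  the density line integral along the diverging ray plus the bolus
  water-equivalent thickness. $D_X$ uses a tail that ramps linearly from 0
  at the surface to the tail level at $R_p$; this is a declared simple
  stand-in for an empirical bremsstrahlung model.
* The inverse-square factor $((100+d_\mathrm{eff})/z)^2$ rescales the
  reference-geometry PDD to the actual point: under bolus, dose appears at a
  shorter source distance than the reference curve assumed, which is exactly
  the mechanism that creates PTV hot spots under thick bolus.
* $G_{\sigma(d)}$ is a row-normalized discrete Gaussian over the fan lattice
  with Fermi–Eyges-style accumulation
  $\sigma^2(d) = \sigma_\theta^2\left[(z_\mathrm{air}+d)^2 -
  z_\mathrm{air}^2\right] + k \int_0^d (d-t)^2 / E_\mathrm{rel}(t)^2\,dt$,
  $E_\mathrm{rel}(t) = \max(1 - t/R_p, 0.1)$. The constant $k$ is calibrated
  per beam so the total lateral spread at depth $R_{90}/2$ in water is
  $0.17\,R_{90}$ cm (0.85 cm for the 16 MeV, $R_{90}=5$ cm study beam).
  Row normalization keeps the kernel exactly mass-preserving at every
  $\sigma$, including the shallow-depth limit where it degenerates to the
  identity.

**Normalization.** 100% is the *given dose*: the maximum central-axis dose
in water for the effective field — the minimum-area rectangle circumscribing
the aperture — at the treatment SSD, without the modulator. It is computed
with the identical discrete machinery so lattice effects cancel.
Output-factor variation with field size is not modelled (a documented
limitation).

A full single-pass redefinition of the pencil-beam phase space at every
layer is intentionally **not** implemented; the single-pass Fermi–Eyges
engine above is the package's segmentation/planning engine.

# Bolus operators

The bolus is a per-fan-line thickness map $t_{ij}$ (cm) with relative
electron density 0.92 (machinable wax; configurable — the value is a
package default, as no standard tabulation applies to every wax blend). The
bolus is modelled as an upstream *range shifter*: it adds $t\,\rho_b$ of
water-equivalent depth along each ray without geometrically displacing the
surface. This "physical depth" reading makes the operator arithmetic exact:

* **Create**$(p\%, m)$ — for fan lines inside the PTV eroded laterally by
  $m$ (isocenter-plane projection): $t = (R_{p\%} - \mathrm{WET}_\mathrm{
  distal})/\rho_b$, floored at 0; other lines take the nearest eligible
  value (height extension).
* **Isodose shift**$(m)$ — one correction pass per call:
  $t \mathrel{+}= (z_{p\%} - z_\mathrm{distal})/\rho_b$ using the deepest
  $p\%$ crossing of the *current* dose; lines without a crossing are left
  unchanged and counted. Ineligible lines are re-extended so the surround
  follows the corrected interior.
* **Smooth**$(e, r)$ — convolution with
  $\exp(-e\,(\rho/R)^2)$, $R = 1.5r$ cm, truncated at $\rho = R$ and
  renormalized over the footprint (edges are not drained; the footprint
  never changes).
* **Specified shift**$(\delta)$ — $t = \max(t + \delta, 0)$; a small
  negative shave is the conventional coverage margin.
* **Truncate** — thickness outside the projected aperture + 0.5 cm set to
  zero; those rays carry essentially no fluence, so in-field dose changes
  by less than 0.5% (tested).
* **Height extension** — nearest-eligible-neighbor fill, Euclidean in the
  isocenter plane, exact ties to the lower linear index (deterministic).

The operator internals beyond their published parameter semantics are
reconstructions, and are documented as this package's own choices.

`run_sequence()` executes an ordered operator list, recomputing dose where
needed, and supports the canonical chest-wall-style sequences: the BECT
sequence (Create, Smooth, two Isodose-Shift/Smooth rounds, Truncate,
Specified Shift) and the IM-BECT extension (Intensity Modulation, then a
reoptimization round of Isodose Shift, Smooth, Specified Shift with the
modulated weights in place).

# Intensity modulation

For each eligible fan line (ray within 0.5 cm inside the PTV edge), the
maximum percent dose $D_\mathrm{max}$ along the ray inside the PTV is
converted to an intensity reduction factor:

$$\mathrm{IRF} = \begin{cases}
  1.000 & D_\mathrm{max} < 100\% \\
  100\%/D_\mathrm{max} & 100\% \le D_\mathrm{max} \le 125\% \\
  0.800 & D_\mathrm{max} > 125\%
\end{cases}$$

The clamp point is $0.80^{-1} = 125\%$ — the unique threshold at which the
ratio branch meets the printed clamp value 0.8 continuously; the published
threshold typography is ambiguous and this continuity argument is the
package's documented reading. The limits 0.8/1.0 are user-configurable
(`modulation` block). Lines outside the margin take the
nearest-eligible value, exactly as bolus height extension. Only one
modulation pass is applied per sequence; iterative re-application with
repeated bolus redesign is exposed through config sequencing but not
optimized.

# Segmentation

A uniform hexagonal array (nearest-neighbor spacing $r = 0.6$ cm, specified
at the 93.5 cm plane) of pins of diameter $d$ blocks the area fraction
$\pi d^2 / (2\sqrt{3}\,r^2)$, so

$$d(r, \mathrm{IRF}) = r\sqrt{\tfrac{2\sqrt{3}}{\pi}(1-\mathrm{IRF})},
\qquad
\mathrm{IRF}(d, r) = 1 - \frac{\pi d^2}{2\sqrt{3}\,r^2}.$$

The eight available pin diameters (0.158 … 0.473 cm) are data, not code
(`pin_catalog()`). Initial segmentation samples the objective IRF at each
lattice site, applies the closed form, and snaps to the nearest catalog
diameter; a site whose continuous diameter is closer to zero than to the
smallest pin (below 0.079 cm, i.e. sampled IRF above 0.9685) gets no pin —
the omission threshold is this package's choice, as is the lattice
orientation (pointy rows parallel to x, on-axis site, rows offset $r/2$,
pitch $r\sqrt{3}/2$), fixed for reproducibility.

`refine()` then iterates: the achieved intensity is the transported fluence
(relative to the open field) at the clinical QA reference geometry (water
entrance at 100 cm SSD, the plane the 2 cm QA depth projects onto), sampled
at the lattice sites. Sites failing `|achieved - objective| > tolerance`
step one catalog position in the correcting direction (including adding or
removing a pin). Within a sweep, sites are visited in row-major order and a
*predicted* achieved map is updated incrementally with the analytic
single-block kernel after each change, so later sites see the running
correction — an error-diffusion dithering that lets mixtures of adjacent
diameters realize objectives between catalog steps. Sweeps stop on success,
on no change, at `max_iter`, or when a pattern state repeats (oscillation),
returning the best state by maximum absolute error. The default tolerance is
0.03 (the 3% QA dose criterion); note that a *mean* achieved intensity
within 0.02 of an off-catalog objective requires a per-site tolerance of at
most 0.02, which is what the dithering tests use. The published
optimization loop's exact criteria are not public; this tolerance-and-step
scheme is a faithful reconstruction of its described behavior and labelled
as such.

# Quality assurance and plan metrics

`planar_dose()` computes the calculated side of clinical QA: the
percent-of-given-dose distribution at 0.5 or 2.0 cm depth in water under the
modulator (0.1 cm pixels). `composite_pass()` applies the clinical
criterion: a point passes when the dose difference (measured − calculated)
is within 3% **or** the distance-to-agreement is within 0.3 cm; points with
calculated dose below 10% are excluded. Whether the 10% threshold is percent
of the maximum or percent of the given dose is ambiguous in clinical usage;
both are supported (`threshold_mode`), percent-of-maximum being the default.
DTA is found at subpixel accuracy by linear interpolation along grid
segments straddling the measured level (levels shared in 0.25-point bins),
capped at 1 cm, and is directional — calculation is the reference surface.
The dose-difference histogram flags the subset below 80% of the given dose.

DVH metrics: cumulative voxel-counting DVH (0.1% bins), $D_x$ by linear
interpolation on the decreasing branch, the homogeneity span
$D_{90\text{–}10} = D_{10} - D_{90}$, $V_{95}$, and V95-matched
normalization between two plans by bisection (0.1 percentage-point match
tolerance) — the standard footing for comparing a BECT and an IM-BECT plan.

# Synthetic fixtures: what they do and do not show

`wavy_slab_phantom()` is the study geometry: a flat-entrance,
water-equivalent 12×12×6 cm slab at 100 cm SSD containing a 6×6 cm PTV with
flat proximal surface at 0.5 cm and a sinusoidal distal surface,
$z_\mathrm{distal}(x) = 3.0 + 0.5\sin(2\pi x/8)$ cm by default. The default
amplitude/period are a gentle, chest-wall-like undulation: strong enough
that the conformal bolus varies by ~1 cm and produces 4–5% PTV hot spots
through the inverse-square mechanism, gentle enough that the 1.5 cm
smoothing radius of the published operator parameters does not fight the
geometry it is asked to conform to. The companion aperture in the examples
and tests is 10×10 cm — roughly 2 cm of field margin around the PTV, the
standard practice needed for lateral scatter equilibrium at the PTV edge
(an 8×8 field visibly pulls the 90% surface shallow along the field
periphery).

What the fixtures do **not** contain: tissue heterogeneity beyond simple
slabs, oblique incidence and varying SSD across the field, irregular
(non-rectangular) apertures in the planning path, and in-scatter from steep
bolus gradients — in real anatomy that in-scatter, not inverse square, is
often the dominant hot-spot mechanism. Passing tests therefore demonstrate
the operator chain and its convergence behavior, not clinical dose accuracy.

# Numerical choices

* Fan-line spacing 0.2 cm at the isocenter plane (0.1 cm for planar QA
  doses); dose grid 0.2 cm; QA pixels 0.1 cm.
* Open-field fluence is rasterized at 0.05 cm and convolved separably before
  sampling; block deficits are evaluated analytically (erf products), so pin
  structure is not resolution-limited.
* The lateral kernel degenerates to the identity when $\sigma$ falls below
  a tenth of the lattice step; row normalization removes lattice-comb error
  at all other widths.
* Ray sampling steps are half the grid spacing (PTV extent, 90% crossings,
  ray maxima) with trilinear interpolation; crossing depths are linearly
  interpolated.
* The practical-range singularity of the scattering-power integrand is
  floored at 10% residual energy, and $\sigma$ is capped at 2 cm (beyond the
  practical range essentially no electron dose remains).
* Problem sizes throughout the tests (60×60×30 voxel phantoms, 71×71 fan
  lines, ~260-pin patterns) were chosen as the smallest grids on which the
  operator arithmetic, scatter equilibrium and segmentation dithering are
  all resolved; a full BECT + IM-BECT planning comparison completes in well
  under a minute on one core.

# Known limitations

* Single-pass Fermi–Eyges transport: no phase-space redefinition per layer,
  so accuracy degrades in strongly heterogeneous media.
* Perfect pin collimation: no electron in/out-scatter at pin sides; real
  measurements can exceed calculation by a few percent beneath heavily
  modulated arrays.
* The x-ray background is a linear-ramp-plus-constant stand-in.
* Output factors do not vary with field size; the given-dose normalization
  uses the circumscribing rectangle only.
* The bolus is a range shifter (water-equivalent thickness per ray); its
  geometric surface displacement and lateral in-scatter are not modelled.
* Pin axial position inside the foam is irrelevant under perfect
  collimation and is not modelled.
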