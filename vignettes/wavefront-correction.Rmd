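---
title: "Sensorless wavefront correction for STED: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorless wavefront correction for STED}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedao)
```

## The problem

A STED microscope narrows its effective point spread function by overlaying
the excitation focus with a donut-shaped depletion beam: fluorophores on the
donut's ring are forced back to the ground state by stimulated emission, and
only molecules inside the central null still fluoresce. The donut is made by
a vortex (spiral) phase on a spatial light modulator (SLM) in the depletion
path; the same SLM carries a blazed grating (to separate the modulated first
diffraction order from stray reflections) and — in this package's subject —
a *correction phase* that compensates wavefront aberrations introduced by
the optics or by thick samples. Aberrations fill, deform or displace the
donut null, which costs both resolution and signal.

Because the depletion beam cannot excite fluorescence, the correction is
found *sensorlessly*: a point scatterer (a 150 nm gold nanoparticle) acts as
a guide star, its back-scattering signal is proportional to the local
illumination intensity, and a genetic algorithm (GA) searches the SLM phase
pattern that maximizes that signal. Correction runs on the Gaussian
(non-vortex) beam; the corrected donut is then obtained by composing the
recovered phase with the spiral mask.

## The optical model and its assumptions

**Scalar Fourier optics.** The focal intensity is
$I(\mathbf{x}) \propto |\mathcal{F}\{A(\mathbf{u})\,
e^{i\varphi(\mathbf{u})}\}|^2$, with $A$ the binary aperture (open unit
disk) and $\varphi$ the composed pupil phase; intensities are normalized so
the unaberrated peak is exactly 1. This is a deliberate design choice: the
correction method is agnostic to the propagator, and a scalar FFT keeps each
fitness evaluation at desk-scale cost. At NA 1.4 with circularly polarized
light the true focal field is vectorial; the consequences of ignoring this
are catalogued under *Known limitations*.

**Conventions.**

* Grid centre at pixel $(n/2+1, n/2+1)$ (1-based) on even grids; azimuth and
  defocus terms use the same centre.
* Aperture is the *open* disk $\rho < 1$, which keeps the mask exactly
  point-symmetric about the centre (a closed disk would include $u=-1$ edge
  pixels whose mirrors fall off-grid).
* Phase wraps into $[0, 2\pi)$ (half-open); SLM levels are
  $L = \lfloor \mathrm{wrap}(\varphi)/2\pi \cdot 256 + 10^{-9} \rfloor
  \bmod 256$ — the $10^{-9}$ absorbs floating-point error for exactly
  representable levels and is far below the $2\pi/256$ quantization step.
* Defocus is the exact spherical cap
  $\varphi(\rho) = \frac{2\pi}{\lambda} z \sqrt{n^2 - \mathrm{NA}^2\rho^2}$
  ($n$ = immersion index), odd in $z$ — which is why corrections recovered
  for front and back focal planes are negatives of each other. It reduces to
  the paraxial parabola at low NA (tested).
* Focal pixel pitch is $\lambda\,\mathrm{fill}/(2\,\mathrm{NA}\cdot
  \mathrm{oversample})$ nm; `oversample >= 2` zero-pads the pupil at least
  2x before the transform, preventing aliasing.
* Zernike modes use Noll indexing with RMS normalization (the adaptive-optics
  standard); a unit coefficient is 1 rad RMS over the disk. Piston, tip and
  tilt are excluded from optimization genomes: they only offset or translate
  the pattern.

**Default optical parameters.** NA 1.4 oil immersion ($n = 1.518$),
depletion wavelength 760 nm, excitation 635 nm, pupil fill 1.0, simulation
grid 128² (the physical 1080×1080 SLM control region is mapped
proportionally — the method is scale-free, and 1080² FFTs per fitness call
would buy nothing).

**Guide-star signal.** The fitness is the focal intensity integrated over a
pinhole of one Airy radius ($0.61\lambda/\mathrm{NA}$, configurable; the
source experiment reports neither pinhole size nor whether the feedback is
peak or integrated, so the integrated default is exposed as config) at the
star position, normalized to the unaberrated ceiling of 1. The physical PMT
voltage is negative with magnitude growing with signal; the simulator
standardizes on maximize-positive. Optional additive Gaussian noise on the
scalar emulates lab noise without modelling PMT physics. A hidden
`aberration_screen` is applied inside the propagator and is never readable
by the optimizer — the black-box constraint of the sensorless setting.

For GA inner loops, `guide_star_engine()` evaluates the focal field only at
the pinhole's focal pixels by a precomputed direct-DFT transfer matrix; it
agrees with the FFT path to round-off (tested at $10^{-10}$) and is ~40x
faster, which is what keeps the acceptance suite inside its time budget.

## The genetic algorithm

Genomes encode the correction in three modes: `segment` (one 8-bit level per
SLM block; the control region holds $n^2 \cdot 9$ blocks, 81 by default —
the count that balances correction accuracy against convergence speed),
`zernike` (coefficients over a declared Noll mode list, default 4–15), and
`mixed` (both, summed at decode). The decode is deterministic, so identical
seeds give bit-identical runs.

The source method specifies no GA hyperparameters; the defaults follow the
wavefront-shaping GA literature it builds on:

| parameter | default | notes |
|---|---|---|
| population | 30 | one all-zero individual is always seeded, so the run can never end worse than uncorrected |
| parents | population/2 | rank-weighted sampling among the top ranks, distinct pairs |
| crossover | uniform | each gene from either parent with probability 1/2 |
| mutation rate | 0.1 → 0.013 | $R(g) = R_f + (R_i - R_f)e^{-g/40}$ per gene |
| mutation step (Zernike) | 0.5 → 0.05 rad | annealed on the same schedule |
| elitism | 2 | guarantees monotone best fitness when noise-free |
| stopping | 300 generations or 30 without improvement | the experiment reports only "dozens of iterations" |

One deviation from a literal reading of the build contract: the Zernike
mutation step is *annealed* rather than fixed. A fixed step large enough to
explore (≳0.3 rad) cannot settle to the ~0.06 rad per-mode precision that a
0.2 rad total residual requires; annealing the step with the same
exponential schedule as the rate is standard GA practice and is what makes
the recovery criterion attainable. Segment genes are resampled uniformly on
[0, 255] as specified.

Mixed mode optimizes the concatenated genome jointly by default (matching
the "combination" description of full correction); nothing in the code
precludes running a Zernike stage first and seeding a segment stage from its
result, but no dedicated two-stage driver is shipped.

## The depletion model

The effective STED PSF uses the standard exponential saturation law
$h_\mathrm{eff} = h_\mathrm{exc}\cdot e^{-\ln 2\,\zeta\, h_\mathrm{dep}}$,
with $h_\mathrm{dep}$ normalized to peak 1 and $\zeta$ the saturation factor
(peak depletion intensity over saturation intensity). The source paper gives
no formula; this one is chosen because $\zeta$ is interpretable ($\zeta = 1$
halves emission at the donut peak) and because it reproduces the textbook
$\mathrm{FWHM} \approx \mathrm{FWHM}_\mathrm{conf}/\sqrt{1+\zeta}$ scaling.

That scaling law is a *single-wavelength* statement: its derivation assumes
the donut's near-axis curvature is matched to the confocal spot width. For a
charge-1 vortex the normalized donut rises as
$h_\mathrm{dep} \approx 0.43\,(2\pi \mathrm{NA}\, r/\lambda_\mathrm{dep})^2$,
so the effective saturation seen by the confocal spot carries a factor
$(\lambda_\mathrm{exc}/\lambda_\mathrm{dep})^2$. At matched wavelengths the
simulated ratios to the law are 1.03/0.99/0.94 at $\zeta = 1/4/16$ (within
the 10% acceptance band); with the 635/760 nm pair the donut is relatively
wider and the ratios drift to 1.10–1.14. The acceptance test therefore
checks the law in its validity regime, both PSFs at the depletion
wavelength; the two-colour system simply does not obey the single-λ closed
form, and pretending otherwise would test the wrong thing.

## Synthetic data: what it emulates, what it does not

* **Aberration screens** stand in for system optics and thick tissue:
  `zernike_random` draws $c_j \sim N(0, 1/j)$ over Noll 4–11 (lower orders
  dominate, as in real optics) and rescales to an exact target RMS (default
  1.5 rad — strong enough to cost ~70–90% of the guide-star signal, the
  regime where correction is worth doing); `defocus` is the spherical cap
  for a stated z-offset (the "artificial system aberration" experiment);
  `spherical` puts the budget in Noll 11; `turbulence` is a Kolmogorov-like
  $f^{-11/6}$ filtered-noise screen. All are single-plane (isoplanatic) and
  bit-reproducible from (recipe, seed). Real tissue is volumetric,
  spatially variant and depth-dependent; none of that is modelled.
* **Phantoms**: bead fields (dart-throwing with a minimum separation,
  optional sub-diffraction close pairs) stand in for 100 nm microspheres;
  filament phantoms (persistent random walks sampled every 25 nm, optional
  width jitter) stand in for immunolabelled microtubules. Brightness is
  constant by default; emitters are points (a 100–150 nm particle at a
  230–280 nm confocal FWHM is effectively a point).
* **Image formation** is convolution with the effective PSF plus optional
  Poisson noise — no background, no detector offset, no drift, no
  photobleaching.

A green test on this world therefore establishes that the *algorithm*
recovers hidden pupil-plane phase from intensity-only feedback under the
scalar model; it does not establish hardware performance, nor the
vectorial-optics effects discussed next.

## Known limitations, and two knowingly red acceptance clauses

**Even-order aberrations cannot fill a scalar vortex null.** The on-axis
field of a charge-1 vortex under aberration $\psi$ is
$E(0) \propto \int A\, e^{i(\theta + \psi)}\,dA$. If $\psi$ contains only
even azimuthal orders (astigmatism $m=\pm2$, defocus, primary spherical
$m=0$), the integrand's azimuthal spectrum contains only odd harmonics
$e^{i(2k+1)\theta}$, which all integrate to zero: the null survives
*exactly*, however large the coefficient (numerically: $10^{-10}$ of the
flat peak at 1 rad of astigmatism, vs $3\times10^{-2}$ for 1 rad of coma,
whose odd order does couple). One acceptance clause asserts that 1 rad of
astigmatism raises the null depth above 0.05; under this package's stated
propagator and centre convention that premise is false, and the clause is
left red rather than redefined. What astigmatism *does* destroy is the ring:
max/min azimuthal uniformity degrades to ~70 at 1 rad, and the GA correction
restores it to ~1.05 — those clauses pass. A companion unit test
demonstrates the null does fill for coma, i.e. the simulator reproduces the
phenomenon whenever parity permits.

**Whole-frame mean intensity does not increase after correction in a scalar
model.** Experimentally, corrected STED images are brighter, because a badly
aberrated donut dumps light into the null and quenches the very fluorescence
being detected. In the scalar model an aberration mostly *displaces and
deforms* the null rather than destroying it; the scanned uncorrected beam
still finds near-full emission at a small offset, while its weakened ring
depletes the surroundings less — so the uncorrected image retains *more*
total fluorescence (measured mean ratios 0.2–0.7 across screen kinds and
$\zeta \in \{4,16,30\}$, under both donut normalizations). The genuine null
fill that drives the experimental brightness gain is, at NA 1.4 with
circular polarization, a vectorial effect (plus SLM nonidealities), both
outside this package's scope. The acceptance clause asserting a mean
intensity increase is left red with this analysis; the resolution clause
(corrected bead FWHM strictly smaller) passes.

**Other numerical notes.**

* Gaussian-fit FWHM of an Airy spot is window-dependent: fitted over
  ±1.2 FWHM it matches the half-max width within ~1.5%; over ±4 FWHM the
  rings pull it ~3% low. Tests and the scenario runner use peak-scale
  windows, as an experimentalist fitting a dotted-line profile would.
* The blazed grating plus first-order pinhole of the physical bench is
  treated as an ideal pass-through (diffraction efficiency 1); the grating
  period is exposed as config and verified to produce a pure focal shift.
* `run_ga` tracks the best *observed* fitness; under fitness noise the
  returned genome is the argmax of noisy observations, and the robustness
  criterion evaluates it noise-free afterwards.
* Degenerate inputs fail loudly: zero spiral charge, grating periods below
  Nyquist, non-finite fitness (with the offending genome named), emitters
  outside the field, flat profiles in the FWHM fitter.

## Reproducibility and I/O

A scenario (JSON) fully specifies grid, screen, guide star, GA, depletion
factors, phantom and a master seed; named sub-seeds per stage (screen, GA,
phantom, imaging) ensure one stage's draw count cannot shift another's.
Every artifact set carries a manifest with the scenario hash, package
version and fitness-evaluation count, so GA-vs-baseline budget comparisons
are auditable. Masks export as 8-bit BMP and binary PGM (level = phase
quantization contract above — the exact SLM payload); no PNG codec ships
with the supported R stack, so PNG is not offered. PSFs and images export as
uncompressed 32-bit-float TIFF with the pixel size embedded both as
resolution tags and as a JSON `ImageDescription`, cross-checked in the test
suite against an independent TIFF implementation.
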