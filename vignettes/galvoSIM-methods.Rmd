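---
title: "Simulating and analyzing single-galvo interference-pattern SIM"
author: "galvoSIM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing single-galvo interference-pattern SIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galvoSIM)
```

## The system being modelled

Structured illumination microscopy (SIM) doubles lateral resolution by
illuminating the sample with fine interference fringes at several
orientations and phases, then computationally demixing the frequency
bands encoded in the resulting images. galvoSIM is a desk-scale
computational twin of a fringe generator in which a *single*
galvanometric mirror controls everything: its coarse angle selects which
column of a miniature mirror array is illuminated — and therefore which
set of mini-lenses forms foci at the back focal plane of the main lens,
i.e. which preset beam combination interferes at the sample — while
micro-rotations of the same mirror advance each beam's optical phase in
proportion to the beam's horizontal offset, shifting the fringe phase
without changing the pattern.

The package simulates this system end to end (beams, polarization,
patterns, camera acquisition of bead phantoms, galvo scheduling with
settling) and implements the analyses such an instrument needs:
fringe-visibility fitting, per-frame Fourier-correlation traces,
transition detection, voltage-to-phase calibration, three-phase SIM band
separation with Wiener recombination, and Fourier ring correlation (FRC)
resolution estimation.

## Optical model

**Beams.** A beam is a focus at pupil position $p$ (mm) in the back
focal plane of the main lens (focal length $f$). The sine condition
$\sin\theta = |p|/f$ maps it to a plane wave with transverse wavevector
$k_t = (2\pi n/\lambda)\, p/f$ and $|k| = 2\pi n/\lambda$; beams must
satisfy $|p| \le \mathrm{NA}\, f/n$. With this normalization a beam pair
at the aperture edge produces the finest fringe, period
$\lambda/2\mathrm{NA}$.

**Polarization.** Pupil-plane Jones vectors are transported onto the
tilted wave by the standard aplanatic rule: the component perpendicular
to the meridional plane (s) is preserved, the in-plane (p) component is
rotated to stay transverse. This reproduces the physics that motivates
s-polarized illumination: two p-polarized beams at tilt $\pm\theta$ have
field overlap $\cos 2\theta$ and lose fringe contrast at high NA, while
s-polarized pairs keep full contrast. A horizontally polarized beam
whose interference plane is rotated $60^\circ$ from horizontal carries
75% of its power in the s component — the side-column geometry — and a
double-passed quarter-wave plate (acting as a half-wave plate) rotates
the center column from p to s.

**Galvo phase.** The fringe-phase mechanism is modelled as
$\phi = g\, x\, \delta\theta$ with $x$ the beam's horizontal offset in
the galvo plane (mm) and $\delta\theta$ the micro-rotation. The gain $g$
is configurable; its default is the physical double-pass reflection
value $g = 4\pi/\lambda$ (a mirror rotation $\delta\theta$ adds path
$2x\,\delta\theta$), which the tests verify against an exact reflection
ray trace. Under this default a full $2\pi$ step across a 2 mm beam
span needs $\approx 0.12$ mrad — about 0.7% of a typical
column-to-column reorientation step, consistent with the phase step
being a tiny fraction of the orientation step.

**Design formulas.** Closed forms are provided for the required galvo
stability $\arctan(\lambda\,\mathrm{fraction}/\mathrm{separation})$
($\lambda/10$ at 488 nm over 2 mm $\approx$ 24 µrad), the Rayleigh
focus diameter $0.61\lambda f/D$, and the field coverage of a
Nyquist-sampled DMD fringe projector. For the DMD bound, the printed
reference values (323 µm × 172 µm inside a 367 µm field, coverage
just under 53%) are reproduced by $\lambda = 473$ nm and
$\mathrm{NA} = 1.5$ with a sample-referred mirror pitch of
$\lambda/4\mathrm{NA}$; this combination was confirmed numerically
rather than assumed.

## Pattern synthesis

A preset is a list of beams; the field on a grid is the coherent vector
sum $E(r) = \sum_j A_j \hat p_j e^{i(k_j\cdot r + \phi_j)}$ and the
intensity its squared modulus summed over components. Three preset
families mirror the instrument configurations: two-beam (sinusoidal,
z-invariant), hexagonal three-beam (three-fold symmetric, z-invariant,
built with azimuthal polarization by default; a "parallel" option
approaches the scalar $9A^2$ phasor-sum limit at small tilt), and
linear three-beam (center + two side beams, periodic along z with
period $2\pi/(k_{z,\mathrm{ctr}} - k_{z,\mathrm{side}})$). Deliberately
asymmetric side beams produce the characteristic beating — alternating
bands of fringes and nodes — and are flagged with a warning.

Relay magnification between the pattern-forming plane and the sample is
folded into the model: patterns are synthesized directly in sample-plane
coordinates with the objective NA as the aperture scale, which keeps
pattern and camera grids commensurate. Grids must sample the finest
fringe with at least two pixels (the default camera uses 65 nm pixels,
2.4 pixels per finest period); synthesis refuses undersampled grids.

## Synthetic acquisition

**Phantoms.** Sparse or dense fields of sub-diffraction beads with a
minimum pairwise separation, plus optional "resolution pairs" at a
stated spacing (default 100 nm) whose surroundings can be kept clear —
as one would choose an isolated pair to measure two-point resolution.
Bead spots are Gaussians with $\sigma = d/4$, the width of a solid
sphere's projected profile for diameter $d$.

**Image formation.** Emission is the pointwise product of the dye
density and the illumination intensity, blurred by a scalar Airy
detection PSF (band limit $2\mathrm{NA}/\lambda$), scaled to expected
photoelectrons, then Poisson shot noise, Gaussian read noise, gain,
offset, quantization and bit-depth clipping. Because the bead spots are
narrower than a camera pixel, the optical product is rendered on an
internally oversampled grid (2× by default) and integrated per pixel;
the illumination is upsampled by Fourier interpolation, which is exact
for a band-limited fringe field. Rendering at the camera pitch directly
would alias the spot spectrum and displace the fringe-encoded bead
positions by tens of nanometres — enough to corrupt two-point
measurements.

**Scheduling.** A `GalvoSchedule` is an ordered list of (orientation,
phase, dwell) entries with a raw frame rate. The default SIM cycle is 3
orientations × 3 phases with the first phase of orientations 2 and 3
held two frames, 11 raw frames per cycle — 89 fps final at 980 fps
raw. The characterization sweep is 3 × 5 positions traversed back and
forth. Frames exposed while the galvo settles are mixtures of the
moving and settled pattern: phase micro-steps contribute the swept-phase
average, orientation changes the fringe-free washed-out level, for the
fraction of the exposure the move occupies (settling defaults: 0.9 ms
for orientation changes, 50 µs for phase steps). At a 3252 fps raw rate
an orientation change therefore spans three frames, at 980 fps one
frame; direction alternation between cycles leaves the first frame of
every cycle clean.

## Characterization analyses

**Visibility.** `fitSinusoid2d` fits
$a(1 + V\cos(2\pi f\cdot r + \phi))$ with the frequency seeded from the
Fourier peak and refined numerically, amplitudes solved linearly at each
trial frequency. On noiseless synthetic patterns it agrees with the
closed-form $V = 2A_1A_2|o|/(A_1^2+A_2^2)$ to $10^{-6}$.

**Fourier-correlation traces.** Following the instrument's own
diagnostic, each frame's Fourier transform is correlated against the
reference's over frequency shifts; by Parseval this is the transform of
the pixelwise product of the two images, so the off-DC peak sits at the
fringe wavevector and its amplitude/argument track fringe visibility
and phase. Three implementation choices matter:

* the widefield (reference) component is subtracted from each frame
  before the product — image formation is linear in the illumination, so
  this removes the object's own DC-centered power exactly and leaves the
  fringe-modulated content;
* peak finding operates on the ring-median-whitened magnitude, so the
  coherent fringe peak is not outcompeted by the low-frequency speckle
  envelope of a bead field;
* frames are clustered by peak position (one cluster per orientation), a
  single sub-pixel frequency is refined per cluster, and all member
  phases are read at that common frequency. A per-frame frequency would
  leak its jitter into the phases through the coordinate origin.

Residual fringe content in the reference (unbalanced phase weighting
from dwell or transition frames) offsets all phasors of a cluster by a
common complex constant; for a balanced full-circle phase set the
plateau mean equals that constant exactly and is subtracted, larger
plateaus use a least-squares circle center. Bead-speckle leakage from
the conjugate fringe component adds a term $Y e^{-i\phi_j}$ whose
relative size scales as $1/\sqrt{N_\mathrm{beads}}$: with at least four
distinct phases the per-bin fields $(X, Y, Z)$ and the phases are
jointly identifiable and an alternating least-squares self-calibration
removes the bias; with exactly three phases the system has zero degrees
of freedom, so three-phase accuracy relies on the dense bead layer the
real characterization sample also uses. Transition frames appear as
clear amplitude minima and are grouped into runs by
`detectTransitions`.

**Calibration and repeatability.** `calibrateGalvo` sequentially
unwraps phases over a fine voltage scan, fits a line, and solves it for
even steps of $2\pi/3$ (2D SIM) or $2\pi/5$ (3D SIM); scans whose
per-point step approaches $\pi$ are rejected as ambiguous.
`phaseRepeatability` compares two traces of the same schedule per
plateau with circular arithmetic, reporting the RMS difference as a
fraction of $2\pi$.

## Reconstruction

`separateBands` solves the per-pixel mixing model
$D_j(k) = b_0 + \tfrac12 e^{i\phi_j} b_{+1} + \tfrac12 e^{-i\phi_j}
b_{-1}$ (least squares for more than three phases; degenerate phase sets
are rejected by singular-value check). The modulation depth stays
folded into the order-$\pm1$ bands. `estimateSimParams` applies the
correlation machinery above per orientation and reports fringe vector,
per-frame phases (up to an object-dependent global offset per
orientation) and a rough modulation estimate.

`wienerReconstruct` upsamples bands onto a 2× Fourier canvas, shifts
each order-$\pm1$ band to its true frequencies by real-space carrier
multiplication (a band $b_{+1}(k) = \mathrm{OTF}(k)\tilde S(k-p)$
shifted to $b_{+1}(\kappa+p)$ carries the detection OTF displaced by
$-p$), estimates the residual global phase and modulation against the
order-0 band over the OTF overlap region (continuously weighted by the
OTF product, which keeps every overlap pixel in play even when the
fringe frequency approaches the detection cutoff), and combines all
bands with generalized Wiener weights
$\hat S = A\,\sum_b \mathrm{OTF}_b B_b / (\sum_b \mathrm{OTF}_b^2 + w)$
plus a triangle apodization to the extended support. Bands whose
estimated modulation falls below 2% are dropped, so the
zero-modulation limit reduces exactly to widefield Wiener
deconvolution. Output is clamped nonnegative. For two-point resolution
probing the apodization is better disabled (it trades contrast at the
support edge for artifact suppression); the bundled acceptance analysis
does so.

`deconvolveWidefield` is a plain Wiener filter against the analytic
Airy OTF; its DC gain is $1/(1+w)$ so energy is preserved to within
$w$. Negative ringing is clamped with the total flux renormalized. In
the large-$w$ limit the output tends to a scaled OTF-filtered copy of
the input (the idealized "scaled input" limit holds only for
low-frequency-dominated scenes).

`frcCurve` computes the radially binned normalized cross-correlation of
two independent images and reports the resolution at the first
threshold crossing (fixed-1/7 criterion by default, linearly
interpolated between rings; identical images report the two-pixel
Nyquist floor).

## Study conditions and problem sizes

Defaults were chosen once to emulate the instrument's demonstrations
and are used by the test suite as fixed study conditions:

* excitation 473 nm, objective NA 1.5 (aperture medium 1.518); emission
  520 nm; camera 65 nm sample-referred pixels, 1.6 e⁻ read noise,
  16-bit;
* characterization: 192² pixel ROI over a dense layer of ~3000 beads
  (100 nm, 12.5 µm field), fringes at 0.85 of the aperture (within the
  detection band), ~5000 peak photoelectrons;
* parameter recovery: 250-bead fields, 192² ROI, 20 seeds;
* two-point resolution: full-aperture fringes (157.7 nm period — beyond
  the 1.45-NA emission cutoff, as in surface-illumination SIM; the
  correlation estimator tolerates this because the product spectrum
  extends to twice the cutoff), emission NA 1.45 reflecting the
  OTF-extending scattering of nanoparticle samples, 500-bead layer with
  isolated 100 nm pairs, a five-phase $2\pi/5$ schedule, 256² ROI.

These sizes keep any single simulated experiment within seconds to a
couple of minutes on one core while leaving clear margins to the
acceptance tolerances.

## What the simulations do and do not show

The generator emulates: sparse and dense sub-diffraction bead samples,
sinusoidal and three-beam illumination with vectorial contrast, shot
and read noise, quantization, galvo settling mixtures and schedule
structure. It does not model: field-dependent aberrations, evanescent
(TIRF) field decay, photobleaching, drift, coherence-length or
path-matching effects, long-term thermal phase drift, or 3D volumetric
imaging (axial structure is evaluated plane by plane; volumetric
reconstruction is out of scope). Passing tests therefore demonstrate
the correctness of the algorithms under the stated image-formation
model, not robustness to every artifact of real hardware; the
measured instrument quantities (fringe visibility 0.92 on the bench,
99 nm / 138 nm FRC resolutions) are properties of physical samples and
optics and are deliberately not reproduction targets.

## Worked example

```{r example, eval = FALSE}
cfg <- opticalConfig()
camera <- cameraModel(roi = c(128, 128))
psf <- widefieldPsf(520, 1.42, 65)
phantom <- generateBeadPhantom(1200, fov = 8.3, min_separation = 0.08,
                               seed = 1)
stack <- runSchedule(phantom, simPresets(cfg), simCycleSchedule(),
                     cfg, camera, psf, seed = 2, n_cycles = 2)
trace <- fourierCorrelationTrace(stack)
detectTransitions(trace)$runs
rec <- reconstructSim(stack)
rec$params
```
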