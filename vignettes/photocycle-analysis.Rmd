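---
title: "Photocycle kinetics from flash photolysis: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photocycle kinetics from flash photolysis: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocyclr)
```

photocyclr implements the computational side of characterizing a microbial
rhodopsin photocycle from laser flash photolysis, built around the
green-absorbing proteorhodopsin E17R (λmax = 524 nm): simulation of transient
absorbance data, logarithmic data reduction, global lifetime fitting,
first-order kinetic modelling (including the kinetically hidden M
intermediate and its blue-light photocurrent shunt), pH-titration and
extinction-coefficient spectroscopy, and spectral-tuning sequence analysis.
This vignette explains the underlying models, the tunable parameters, and the
design decisions taken where the methodology left choices open.

## The kinetic model

After a nanosecond excitation flash, a fraction of the protein enters a cycle
of spectrally distinct intermediates and relaxes back to the dark state. All
steps are first order, so the state populations obey

$$\frac{d\mathbf{c}}{dt} = K\,\mathbf{c},$$

where column $j$ of the rate matrix $K$ holds the rate constants out of state
$j$ and the diagonal closes the mass balance. `simulate_populations()` solves
this exactly by eigen-decomposition — no step-size error on any time grid —
and rejects defective (non-diagonalizable) matrices with advice to perturb
nearly equal rates; the independent check in the test suite integrates the
same equations with an adaptive ODE solver.

The observable is the transient absorbance change

$$\Delta A(\lambda, t) = c\,l\,f_{exc} \sum_s c_s(t)\,
  \bigl(\varepsilon_s(\lambda) - \varepsilon_G(\lambda)\bigr),$$

with $c\,l$ the Beer–Lambert factor and $f_{exc}$ the cycling fraction
(default 0.15). Each state's extinction $\varepsilon_s(\lambda)$ is a
(possibly skewed) Gaussian band, parameterized by center, FWHM and peak
extinction. Because the dynamics are linear, $\Delta A$ is exactly a sum of
exponentials whose lifetimes are $-1/\lambda_i$ of the kinetic eigenvalues and
whose amplitudes are the decay-associated spectra (DAS); `predict_das()`
computes both in closed form, and round-trips with the global fit on
noiseless data.

### The default E17R scheme

`e17r_scheme()` encodes the photocycle deduced for E17R: a ground state at
524 nm (peak extinction 50,000 M⁻¹cm⁻¹, FWHM 100 nm) and a linear chain of
four red-shifted intermediates whose sequential decays carry lifetimes of
3.5 µs, 84 µs, 11 ms and 82 ms, the last being dark-state recovery. The
first intermediate forms below the instrumental time resolution, expressed by
placing the whole t = 0⁺ population on it. Four kinetic modes are used
because four exponentials are what the transient data resolve.

Band positions and amplitudes of the intermediates are not published as
numbers, so they are free fixture parameters. They were chosen once, from an
identifiability argument: adjacent intermediates carry distinct bands
(560/545/590/600 nm, FWHM 100–120 nm, peaks 40,000–45,000 M⁻¹cm⁻¹) so that
*every* kinetic component has a DAS of the order of 10 mOD at the default
sample geometry (10 µM, 1 cm, absorbance 0.5 OD at 524 nm). Had two adjacent
states identical spectra, the corresponding lifetime would have amplitude
zero and be unrecoverable from data that, by construction, should constrain
it. All intermediate extinctions at 524 nm stay below the ground state's, so
the transient at the dark-state maximum is a pure bleach.

### The hidden M state

A deprotonated-Schiff-base (M) intermediate absorbing near 400 nm must exist
for proton pumping, yet leaves no signature in the transient spectra. The
kinetic explanation is quantified by `max_transient_occupancy()`: for a
sequential step with formation rate $k_1$ and decay rate $k_2$, the peak
fractional occupancy is $(k_1/k_2)^{k_2/(k_2-k_1)}$, with the matched-rate
limit $1/e$. When formation and decay are similarly fast the state never
accumulates beyond that, and its 400 nm band — far from the strong visible
difference bands — stays within measurement noise.

Exactly matched rates make $K$ defective (a Jordan block: the analytic
solution would need $t\,e^{-kt}$ terms), which the eigen-based engine
rejects. Three requirements — an explicit matched-rate M, a four-mode default
chain, and diagonalizability — cannot hold simultaneously, so the package
resolves them as follows: the default scheme is the diagonalizable four-mode
chain (what the data show); `e17r_scheme(include_m = TRUE)` inserts an
explicit M after the 84 µs step with a small relative rate split (default
5%, peak occupancy still ≈ 1/e); and the exactly matched case is handled
analytically by `max_transient_occupancy()`.

`steady_state_current()` models the companion photocurrent experiment: under
continuous green excitation the cycle reaches a photostationary state (the
null space of the augmented rate matrix); blue light that excites M back to
the ground state opens a shunt that bypasses proton release, so the pumped
current — the flux through M's productive decay, reported relative to the
blue-off current — strictly decreases with blue intensity. The model is
dimensionless and relative; no capacitive or voltage effects are included.

## Data acquisition and logarithmic reduction

`default_acquisition()` mirrors the experiment: 14 probe wavelengths
(380–645 nm), a flash at 503 nm defining t = 0, and two oscilloscopes
digitizing 46,080 samples each at 200 ns/point and 20 µs/point, the first
sample one dwell time after the flash. The raw count is read as 45 × 1024
("45k"); this is the only reading consistent with the 880 reduced points
below. Gaussian noise (default σ = 0.3 mOD, independent per sample) emulates
the trace quality of the measurement; all randomness flows from one integer
seed and outputs are bit-reproducible.

`reduce_log_blocks()` compresses each uniform trace century-wise: the n-th
century emits 100 points (configurable), each the exact arithmetic mean of
$2^{n-1}$ consecutive samples, the final partial century emitting as many
full blocks as fit, incomplete tail discarded. Design choices: a "century"
emits a fixed 100 points (this uniquely reproduces 880 points from 46,080
samples: eight full centuries plus 80 blocks of 256); block timestamps are
the mean of member sample times (unbiased for uniform sampling); short tail
blocks are discarded rather than averaged short (uniform within-century
variance). Averaging is implemented rather than interpolation onto an exact
logarithmic grid: block means keep every reduced point an exact mean of raw
data, recoverable from the provenance. `merge_traces()` then keeps all fast
points plus the slow points whose block-center time strictly exceeds the last
fast time, giving 1520 points up to ~0.92 s for the default acquisition.

## Global fitting by variable projection

`fit_global()` fits all wavelengths simultaneously to
$\sum_i A_i(\lambda)\,e^{-t/\tau_i}$ with shared lifetimes. At fixed
lifetimes the amplitude matrix is the solution of a linear least-squares
problem, so it is eliminated by QR projection and the nonlinear search
(Levenberg–Marquardt via minpack.lm) runs only over $\log\tau$ — positivity
is structural and lifetime ratios are searched on their natural scale.
Choices that the original analysis leaves unstated, and their defaults here:

* **No additive offset.** The photocycle recovers the ground state fully, so
  the model is a pure exponential sum; `offset = TRUE` adds a per-wavelength
  constant when needed.
* **Unweighted least squares.** Block averaging makes late points less noisy;
  `weighting = "block"` rescales residuals by $\sqrt{\text{block size}}$
  (inverse standard deviation), but the default matches the plain global fit.
* **Multistart.** Without initial values, one evenly log-spaced start plus
  four starts drawn log-uniformly from $[2\min\Delta t,\ 2\max t]$ under a
  fixed internal seed; the best optimum is kept, so results are reproducible.
* **Convergence.** Relative cost change below $10^{-10}$ or 500 iterations;
  ties in the recovered lifetimes are broken by ascending sort with DAS rows
  carried along. A relative standard error per lifetime is derived from the
  projected-residual Jacobian as a covariance proxy.

`select_n_exponentials()` picks the component count by diminishing returns:
the model is truncated at the first component improving the residual rms by
less than 5% (configurable); residuals already at numerical noise relative to
the data end the search regardless of the ratio.

## pH titration and extinction spectroscopy

The absorption maximum of the protein titrates with pH through two
transitions, modelled as a double Henderson–Hasselbalch curve
(`titration_curve()`): an acidic transition (pK₂, counterion protonation,
red shift toward 535 nm) and a basic one (pK₁, smaller shift from 517 to
525 nm). `fit_titration()` fits midpoints and plateaus by nonlinear least
squares; Hill coefficients are fixed at 1 by default (`free_hill = TRUE`
relaxes this). The observable fitted is λmax(pH) — what the titration figure
plots — though any scalar observable column (e.g. absorbance at a fixed
wavelength) can be supplied, since the experimental choice is not stated.
When no data lie below the acidic midpoint (experimentally, pH < 2 denatured
the protein), the acid plateau is flagged as an extrapolated parameter.

The extinction coefficient is calibrated against the retinal oxime formed on
hydroxylamine bleach (ε = 33,600 M⁻¹cm⁻¹):
$\varepsilon_{Rh} = \varepsilon_{oxime}\,\Delta A(Rh)/\Delta A(oxime)$, with
both amplitudes read as the extrema of the after-minus-before difference
spectrum, as in the experimental procedure. For overlapping bands each
extremum carries the other band's Gaussian tail, so the calibration is exact
only for spectrally separated bands; at the E17R positions (524 vs ~360 nm)
with realistic 80–100 nm widths the overlap limits accuracy to roughly one
part in 10³–10⁴, which the tests assert explicitly alongside the exact
separated-band round-trip.

## Sequence-level spectral tuning

Green and blue proteorhodopsin subfamilies differ by a single tuning-switch
residue (BPR position 106; E17R position 94): leucine tunes green, glutamine
blue. `classify_spectral_tuning()` aligns a query to a BPR-numbered reference
and reads the homologous residue; `map_key_residues()` transfers annotated
functional positions (proton acceptor D86, lysine proton donor K97, the
acceptor-stabilizing histidine H58, Schiff-base lysine K226 in E17R
numbering) through the alignment, verifying residue classes. Alignments are
deterministic pairwise global alignments (BLOSUM62, gap open 10 / extend
0.5, via Biostrings), with an end-gap-free variant behind a flag; percent
identity counts identical pairs over aligned columns containing at least one
residue. A multiple-sequence aligner is deliberately not used: only pairwise
identities and position transfers are needed, and a deterministic pairwise
method keeps them reproducible. Published identity percentages come from an
unstated aligner, so ±1 percentage point around rounded values is the
expected agreement.

Because the real accessions require a database download, the package ships
`synthetic_pr_sequences()`: deterministic synthetic stand-ins (clearly
labelled as such) engineered with the structural relationships that matter —
the 248-residue (744 coding bp) query with its key residues, a relative with
the one-residue N-terminal offset and 7-residue loop insertion that reproduce
the D85/K96/H57/K232 numbering and an 85% rounded identity, and a
blue-tuned reference with a 12-residue N-terminal extension placing the
glutamine switch at position 106. They exercise the full analysis path
offline; they are not the real proteins.

## What the generator does and does not emulate

The synthetic data reproduce the acquisition geometry, the four-lifetime
kinetics, sub-resolution formation of the first intermediate, full
ground-state recovery, and independent Gaussian noise of realistic magnitude.
They do **not** include instrument-response convolution beyond instantaneous
formation, photoselection/anisotropy, shot noise or baseline drift,
wavelength-dependent noise, or pH/temperature dependence of the rates.
Passing lifetime-recovery tests therefore demonstrates the correctness of the
reduction and fitting machinery under the stated noise model — not robustness
to every artifact of real spectrometers.

## Numerical choices and problem sizes

Eigen-decompositions reject matrices with eigenvector condition number below
`rcond` $10^{-12}$ (defective) and, for DAS prediction, eigenvalue pairs
closer than $10^{-9}$ relative (degenerate). Population columns are
guaranteed to sum to 1 within $10^{-10}$. Trace TSVs are written with 9
significant digits (lossless round-trip at that precision); every pipeline
output embeds an MD5 hash of the configuration, so equal configurations give
byte-identical outputs. The test suite runs the full-size experiment
(2 × 46,080 samples × 14 wavelengths, 1520 fitted points) for the
acceptance-level checks and smaller geometries (a few thousand samples, 2–5
wavelengths) for the unit and property suites; Monte-Carlo recovery studies
use 20 seeds.

## Known limitations

* The photocycle topology is not uniquely determined by four exponentials;
  the linear chain is one consistent choice, and branching schemes are
  expressible through the rate matrix but not fitted (no target analysis with
  spectral constraints, no lifetime-distribution analysis).
* DAS amplitudes are fixture parameters, so only lifetime recovery — not
  amplitude values — is checked against published constants.
* The titration model assumes independent transitions; strongly overlapping
  pKs (closer than 0.5 units) are flagged, not modelled.
* The photocurrent model is photostationary and relative; capacitive
  transients and voltage dependence are out of scope.
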