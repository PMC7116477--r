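---
title: "Directed functional connectivity with npdirect: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed functional connectivity with npdirect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

npdirect estimates frequency-resolved directed functional connectivity (dFC)
between continuous neural signals — local field potentials, EEG or MEG virtual
sensors — and provides the simulation and statistical machinery needed to
validate such estimates against known ground truth. This vignette documents
the models and algorithms, the tunable parameters and their defaults, and the
design decisions taken where more than one reasonable construction exists.

## Spectral estimation and coherence

All estimators start from the cross-spectral density matrix `S(f)` estimated
by `spectral_matrix()`: the time series is cut into disjoint segments of
`seg_len` samples (default 256, about 1.3 s at the default 200 Hz sampling
rate), each segment is demeaned, tapered with a power-normalized Hanning
window, Fourier transformed, and the outer products of the coefficients are
averaged across segments. Disjoint (non-overlapping) segments are used; this
is the conservative reading of segment-averaged periodogram estimation, makes
the segment count equal to `floor(T / seg_len)`, and keeps segments
statistically independent for the surrogate machinery. Epoched recordings are
handled by the same path: each epoch contributes its integer number of
disjoint windows.

Magnitude-squared coherence is the normalized cross-spectrum

$$|R_{YX}(\omega)|^2 = \frac{|f_{YX}(\omega)|^2}{f_{XX}(\omega)\,f_{YY}(\omega)} \in [0, 1],$$

a frequency-domain squared correlation. It is symmetric: it carries no
information about the direction of the dependence. Frequencies at which an
autospectrum vanishes yield `NA` rather than 0 — absence of power is not
absence of association evidence. The DC bin is excluded from every
connectivity summary in the package.

## Non-parametric directionality (NPD)

NPD assigns direction by the *time lag* of the dependence. The spectral
matrix is first pre-whitened in the minimum-mean-squared-error sense
(`prewhiten()`): every cross-spectrum is divided by the geometric mean of its
two autospectra, which sets all autospectra to exactly 1 and makes the
squared magnitude of the whitened cross-spectrum equal to the coherence.
Pre-whitening removes each signal's autocorrelation structure — the analogue
of factoring out the "restricted model" in Granger causality — so that the
inverse Fourier transform of the whitened cross-spectrum,
`lag_correlation()`, is a clean lag-domain correlation function
$\rho_{YX}(\tau)$ free of spurious peaks from within-channel periodicity.

`npd_decompose()` splits $\rho$ into three masked sequences — negative lags
(reverse, $Y$ leading), the single zero-lag bin (instantaneous), positive
lags (forward, $X$ leading) — transforms each back to the frequency domain,
and rescales the three magnitude-squared spectra at each frequency by their
relative magnitudes so that they sum *exactly* to the coherence. Scalar
summaries integrate $\rho^2$ over the same lag ranges and, by Parseval,
account for the frequency-mean coherence. Two discrete-grid choices are worth
recording:

* The lag grid runs over one full circle, $\tau = -(L/2-1), \dots, +L/2$ for
  segment length $L$. The single bin at $\tau = L/2$ is direction-ambiguous
  ($+L/2$ and $-L/2$ coincide on the circular grid); it is pooled with the
  symmetric zero-lag component. This keeps three exact identities
  simultaneously: per-frequency additivity, Parseval for the scalar
  components, and exact label swapping
  (`forward(i, j) == reverse(j, i)`) under argument exchange. The bin's
  energy is negligible for spectra that are smooth on the segment scale.
* No lag window is applied to $\rho(\tau)$ before the component transforms;
  the decomposition uses the raw masked sequences.

Frequencies where the coherence is numerically zero get a 0/0 guard: all
three components are set to zero there.

## Conditioned NPD

`partialize()` removes the linear contribution of a reference channel $Z$
from every remaining auto- and cross-spectrum with the standard
single-predictor complex regression
$f_{ab|z} = f_{ab} - f_{az} f_{zb} / f_{zz}$, and `conditioned_npd()` runs
the identical pre-whitening/decomposition pipeline on the partialized matrix,
so the three components now add to the *partial* coherence. For a fully
observed serial route $X \to Z \to Y$ the partial coherence is identically
zero (the package verifies this to numerical precision on closed-form
spectra); as observation noise obscures $Z$, conditioning loses its grip and
the estimate relaxes back to the unconditioned NPD. Only single-reference
conditioning is provided, matching the triadic experiments the package
emulates.

A practical caveat documented here because it surprises users: when the
reference is *near-perfectly* coherent with both members of the pair
(denominators $1 - C \to 0$), the partial coherence becomes a ratio of small
estimated quantities and its sampling variability is amplified at exactly the
peak frequencies. With the default study conditions (segment length 256,
$T = 5 \times 10^4$, coupling 0.5, pole radius 0.75) this regime is not
entered; it appears when coupled resonators are pushed towards determinism.

## Non-parametric Granger causality (NPG)

`wilson_factorize()` implements Wilson's iterative algorithm for factorizing
a Hermitian spectral matrix into a minimum-phase transfer function and a
noise covariance, $S(\omega) = H(\omega) \Sigma H(\omega)^*$, on the full
two-sided grid obtained by Hermitian extension. The causal factor is
initialized from the Cholesky factor of the frequency-averaged spectrum; each
iteration applies the causal-part operator (half the zero-lag coefficient,
upper-triangularized to fix the unitary ambiguity; anticausal lags zeroed).
Iteration stops when the relative update falls below `tol` (default 1e-9) or
when it stalls at the floor imposed by the finite lag grid: a spectrum whose
autocovariance extends beyond `seg_len/2` lags cannot be reconstructed
exactly on that circular grid, so sharply peaked spectra bottom out at a
residual of roughly the truncated covariance mass (about 1e-4 relative for
the default study conditions; 1e-9 or better for gentle spectra, and exact —
via the cepstral construction — for single channels). The final
reconstruction residual is checked against `resid_tol` (default 5e-2) and
returned for inspection. Factorizing on a longer grid (e.g. `seg_len = 1024`)
drives both the residual and the Granger spectra to oracle accuracy; the
package's tests compare against parametric Geweke spectra computed directly
from the true MVAR coefficients.

`pairwise_npg()` factorizes the 2-by-2 submatrix of the chosen pair
(pairwise analysis is deliberately kept distinct from the multivariate
estimator) and evaluates Geweke's frequency-domain measure: the log ratio of
the target's total power to its intrinsic power after the source's
noise-corrected contribution is removed. Small negative values are floating
point artifacts, clipped to zero and counted in `n_clipped`. The
instantaneous term is reported *unclipped*: around strong lagged peaks it can
go negative and uninterpretable, and hiding that would mislead.

`multivariate_npg()` offers two constructions, because the literature and the
established MATLAB toolboxes genuinely differ:

* **conditional** (default): Geweke's conditional causality given all
  remaining channels, via dual factorization — the full matrix and, per
  source, the reduced matrix without that source are factorized, the reduced
  causal factor is embedded in the full space, and a normalization transform
  aligns the innovation bases. This is the mathematically complete
  conditional measure: a fully observed relay $X \to Z \to Y$ yields zero
  conditional $X \to Y$.
* **full**: the pairwise Geweke formula evaluated with the transfer function
  and noise covariance of the single full-system factorization. This is the
  convention of the widely used field toolboxes. It suppresses *lagged
  common drive* (the full model has no cross-transfer between the driven
  nodes) but does not partial intermediate channels out of a pair, so a
  relay still registers as direct causality — which is exactly the behaviour
  reported for this estimator in the validation literature the package
  reproduces, and why the confound sweeps record both variants.

Near-singular spectra (deterministic relays, extreme mixing) can defeat the
factorization; `diag_loading` adds `1e-8 * trace/N` to the diagonal, is off
by default, and announces itself when applied. Conditional estimates, like
all Geweke log-ratio measures, are numerically delicate at frequencies with
very little power (the bottom of resonator spectra near Nyquist); peak-based
summaries are unaffected.

## The MVAR simulator and observation model

`build_periodic_model()` realises each node as a second-order autoregressive
resonator — diagonal coefficients $2r\cos\theta$ at lag 1 and $-r^2$ at lag 2,
a complex pole pair at radius $r$ and angle $\theta = 2\pi f_0/f_s$ — and
each directed edge as a single off-diagonal coefficient (default 0.5) at the
edge's integer lag. Defaults: $f_0 = 55$ Hz at $f_s = 200$ Hz, $T = 5 \times
10^4$ samples (250 s), unit innovation covariance, zero constants. The pole
radius defaults to $r = 0.75$ and is shrunk in 0.01 steps until the coupled
model passes the companion-matrix stability check (`is_stable()`); an error
is raised if no stable radius exists. The radius is the one genuinely free
parameter of the node dynamics: it sets how strongly coupled pairs cohere.
$r = 0.75$ is calibrated so that a directly driven pair of the three-node
common-drive network shows a forward coherence/NPD peak of about 0.6 in the
noise-free condition — the working point of the validation experiments this
simulator emulates. Larger radii push coupled resonators toward determinism
(coherences above 0.9), which is outside the regime those experiments probe.

`observe()` maps latent signals to recordings: mixing by a unit-diagonal
matrix $L$, per-channel z-standardization, then additive white Gaussian noise
scaled by $\lambda$ per channel. Narrowband SNR is defined as
$10\log_{10}$ of the band-mean signal power over band-mean noise power,
with the band defaulting to the spectral peak ±5 Hz (50–60 Hz for the default
model). `lambda_for_snr()` inverts the monotone SNR(λ) map in closed form
against the flat unit-noise density and round-trips within ±0.5 dB.

Mixing strength is specified *operationally* as target shared variance: the
mean squared zero-lag correlation between observed channel pairs, solved
numerically by `calibrate_mixing()`. The alternative — reading the mixing
coefficient itself as "percent shared variance" — is not adopted because the
two conventions cannot be reconciled across the reported uses; the squared
correlation is the measurable quantity and is therefore made the interface.

## Surrogate statistics

`phase_randomize()` keeps every channel's Fourier amplitudes exactly and
draws fresh uniform phases independently per channel (conjugate-symmetric,
DC and Nyquist untouched), nulling cross-channel dependence while preserving
each autospectrum. `permutation_threshold()` evaluates a metric on `n`
surrogates (default 1000; 100–200 is the desk-scale setting used in the
package's own tests) and returns an empirical percentile with the
inverse-ECDF convention, so 1000 realizations at the 99.9th percentile give
the second-largest sample. The default pooling is the **max statistic**
across frequency bins: the threshold then controls the family-wise error of
"any bin significant" across the spectrum, matching the single horizontal
confidence line drawn per spectrum in this literature. Per-bin pooling is
available (`pool = "none"`); the choice is a convention, and it is kept
configurable because the literature rarely states it.

## The graph-recovery benchmark

`run_benchmark()` ties everything together: random 3-node graphs
(`random_graph()`, uniform distinct ordered pairs, uniform lags in 1–3;
graphs whose induced model cannot be stabilized are redrawn with a bounded
retry count), simulation, optional confounds, directional spectra by NPD,
pairwise NPG or multivariate NPG, per-pair surrogate confidence limits at the
99.99th percentile, and the detection rule: an edge is declared when at least
10% of the non-DC frequency bins exceed the pair's threshold. Predictions are
scored ±1 per off-diagonal adjacency cell and reported as a percentage of the
maximum (+6 → 100% on three nodes). For the combined-confound grids, noise
achieving the target SNR asymmetry is applied to the edge-target nodes
*before* mixing, with the weakest signal clamped at +12 dB. The full-spectrum
(0, Nyquist] bin count is used for the 10% rule; restricting to a band is a
config choice.

## Problem sizes and reproducibility

Every stochastic step takes an explicit integer seed, and sweeps derive
per-condition child seeds, so all results in the tests and the acceptance
script are bit-reproducible. The package's own validation runs use
$T = 5\times10^4$ samples per condition, SNR grids at 2.5–10 dB spacing, 100
surrogate realizations per condition, and 24 random graphs with 100 trials of
$2^{10}$ samples for the data-length benchmark — sizes chosen so the entire
suite runs on a single CPU in minutes while keeping estimator scatter well
inside the tolerances asserted.

## What the simulator does and does not emulate

The generator produces stationary, linear, Gaussian oscillators with fixed
lags and stationary observation confounds. Passing validation against it
demonstrates correctness of the estimators and their documented robustness
ordering under *these* conditions. Real neural recordings add
nonstationarity, nonlinearity and non-Gaussianity, state-dependent coupling,
1/f backgrounds, and artifacts; none of these are represented, and results
here do not certify behaviour under them. Point-process (spiking) data and
wavelet/time-resolved variants of the decomposition are likewise out of
scope, as are time-reversal surrogates and alternative directed measures
(transfer entropy, directed transfer function, partial directed coherence).

## Known limitations

* Wilson factorization accuracy is grid-limited for sharply peaked spectra;
  use longer segments when the factorization residual matters.
* Conditional Granger spectra are unreliable at frequencies with very little
  power; use peak or band summaries.
* Partial coherence inflates near unit coherence between reference and pair.
* The logistic summary (`fit_logistic()`, $y = A/(1+e^{-\kappa(x-x_0)})$,
  $\kappa$ per dB, fitted on the dB axis since midpoints are reported in dB)
  assumes a saturating monotone response; fits with $R^2 \le 0.95$ are
  flagged rather than suppressed.
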