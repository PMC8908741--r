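---
title: "Granger causality analysis of folding trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger causality analysis of folding trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grangerfold)
```

This vignette documents the statistical models behind `grangerfold`, the
assumptions they rest on, the tunable parameters and their defaults, what
the synthetic generators do and do not emulate, and the numerical and
design choices made where the problem left the design genuinely open.

## The MVAR / Granger model

The core object is a multivariate autoregressive (MVAR) model of order P
for a K-channel, zero-mean, unit-variance signal $x(t)$ sampled every
$\Delta t$ nanoseconds:

$$x(t) = \sum_{p=1}^{P} A_p\, x(t - p\Delta t) + \Delta x(t),$$

with the residual $\Delta x(t)$ assumed to be white noise with stationary
covariance $V$. The model is linear and stationary by construction; it is
fitted by the Yule–Walker method, i.e. by solving the $P+1$ matrix
equations that relate the coefficient matrices to the lagged second
moments $\Gamma(r) = \langle x(t)\,x^\top(t - r\Delta t)\rangle$
(`estimate_moments()`, `fit_yule_walker()`). Moments are computed with the
biased convention (divide by the number of valid lag products), which
keeps the implied autocovariance sequence positive semidefinite and the
fit stable. Lag products that would span a segment break — between
split-half parts, concatenated trajectories, or shuffled-null surrogates —
are excluded rather than papered over by concatenation.

Two consequences of the Yule–Walker choice worth knowing:

* the fitted $V$ and the empirical covariance of the one-step residuals
  (`predict_residuals()`) agree only to $O(1/T)$, not exactly — exact
  agreement is a property of least-squares (conditional) estimation;
* estimates inherit the $1/\sqrt{T}$ convergence of the moments, which the
  test suite checks explicitly at $T \in \{10^3, 10^4, 10^5\}$.

The model order is chosen by the Schwarz–Bayes criterion,
$\mathrm{SBC}(P) = \ln\det\hat V_P + P K^2 \ln N / N$, with ties broken
toward the smaller order; on data sampled with a long stride the criterion
is typically flat and the most parsimonious model $P = 1$ is adopted.

The Granger coupling from channel $j$ to channel $i$ is

$$J_{j\to i} = 1 - \frac{V_i}{V_i^{(j)}},$$

where $V^{(j)}$ is the residual covariance of the reduced model fitted
without channel $j$. Reduced models are fitted from the
$(K-1)\times(K-1)$ submatrices of the already-estimated $\Gamma(r)$ —
mathematically identical to re-estimating moments on the reduced channel
set (a property enforced by an oracle test against brute-force refits) and
cheaper by a factor of K. The diagonal of $J$ is undefined
(self-causality) and excluded from all descriptor sums, which makes
$\sum_i G^\circ_i = 0$ an exact algebraic identity. Floating-point
negatives above $-10^{-6}$ are clipped to zero; anything below that bound
indicates an internal inconsistency and raises an error rather than being
silently absorbed.

## Significance testing

`shuffle_null_test()` destroys temporal structure by permuting entire
frames — all channels together — which preserves the instantaneous
cross-correlations and the marginals while removing every lagged
dependency. Descriptors are recomputed for each of $n \ge 20$ independent
permutations, the normality of the null ensemble is checked
(Shapiro–Wilk; a failure warns but does not abort), and the observed
category mean is compared to the null ensemble with a Student-t statistic
in its prediction-interval form,

$$t = \frac{\bar G_\mathrm{obs} - \bar G_\mathrm{null}}
           {s_\mathrm{null}\sqrt{1 + 1/n}}, \qquad \mathrm{df} = n - 1.$$

The $\sqrt{1+1/n}$ factor matters: it asks whether the observed value
could be *one more draw* from the null ensemble. Scaling by the standard
error of the null mean instead would shrink with $n$ while the scatter of
the observed value does not, producing spurious significance at large
$n$. Because the permutations reuse the observed sample, the test errs on
the conservative side under a true null (p-values concentrate above
uniform, never below); the suite verifies that the false-positive rate at
the 0.05 level stays within binomial bounds.

## Reaction coordinate and pathway machinery

TICA (`fit_tica()`) solves the generalized eigenproblem
$C_\tau v = \lambda C_0 v$ with a symmetrized lagged covariance (the
average of forward and backward lag products), which guarantees real
eigenvalues and makes the estimator invariant under time reversal — the
natural choice for reversible equilibrium dynamics. "Kinetic mapping"
multiplies each projection by its eigenvalue so that Euclidean distances
in projection space approximate kinetic distances; it is the metric used
for the medoid representative structures. Component signs are fixed
(largest-magnitude loading positive) so results are deterministic.
Rank-deficient feature sets (constant or collinear columns) are rejected
with the offending feature names rather than regularized silently.

Coordinate quality is judged by the Best–Hummer criterion: the
conditional probability $p(\mathrm{TP}|\xi_i) = N_i^{TP}/N_i$ of being on
a transition path, binned (default 50 bins) across the region between the
two core states, whose maximum approaches 0.5 for an ideal coordinate of
diffusive dynamics. Empty bins are undefined and excluded from the
maximum — a ratio with $N_i = 0$ has no value, and zero-filling would
bias the profile. Two core conventions are supported, and the distinction
is substantive:

* **interval cores on $\xi$ itself** — used when validating a coordinate
  against its own dynamics (the diffusive-limit check);
* **a fixed per-frame core labelling** from the reference state
  assignment — used by `rank_trial_coordinates()`. Re-deriving cores from
  each candidate would let an uninformative candidate score deceptively
  well: an i.i.d.-scrambled coordinate enters and leaves its "cores" in
  single-frame flickers, and about half of those flicker gaps connect
  opposite cores, driving its naive $p(\mathrm{TP}|\xi)$ toward 0.5
  everywhere. With transition paths fixed by the actual state definitions
  the scrambled candidate collapses to the overall TP fraction, and the
  true coordinate wins by a wide margin.

The pathway stage follows the standard protocol: PMF from the binned
coordinate density with the global minimum pinned at exactly 0; folded and
unfolded minima located automatically as the pair of local minima
separated by the highest intervening barrier (manual override supported);
six equidistant state centers between the minima with nearest-center
assignment (ties to the lower index); a median filter over the state
sequence whose width is forced odd in frames (1 ns at 0.2 ns stride = 5
frames) so the integer median is unique; committor estimates that follow
each visit of an intermediate state to whichever core it reaches first;
and folding/unfolding events defined by the last-exit/first-entry
convention, with the duration measured from the first frame after the
last U frame to the first F frame inclusive (the endpoint convention is a
choice; alternatives shift every duration by one frame stride).
Uncertainties follow the block conventions of the profiles: ±1 SD over
five consecutive disjoint blocks for PMF and p(TP|ξ), min–max range over
the five blocks for the committor.

The native-ensemble overlap $\Omega(\xi)$ fits a normal distribution to a
distance channel in each of 21 bins between the minima and computes the
overlap area with the folded reference bin analytically from the Gaussian
intersection points (verified against numerical integration); the profile
is then rescaled so its range of variation spans exactly [0, 1].

## What the synthetic generators emulate

`simulate_var()` produces exact realizations of the stated VAR process
(Gaussian innovations, burn-in of max(100, 10P) frames, stationarity
enforced via the companion-matrix spectral radius at construction). It
emulates the statistical skeleton that the Granger machinery assumes —
and nothing else: no nonlinearity, no heavy tails, no nonstationarity.

`simulate_toy_folder()` emulates the phenomenology of a two-state folder
watched through distance-like observables: an overdamped Langevin walker
(Euler–Maruyama, kT = 1) on the double well $U(x) = d(x^2-1)^2$ with
barrier $d = 4\,kT$ and step $h = 0.005$ — small enough that the noise
displacement per step (≈0.1) finely resolves the inter-well distance, so
the dynamics is genuinely diffusive on the recorded timescale and the
$p(\mathrm{TP}|\xi)$ maximum of the true coordinate reaches the 0.5
limit; at $10^6$ steps the trajectory contains a few hundred transitions.
Channels are sigmoids of the coordinate with additive Gaussian noise
(SD 0.1 against a level separation of order 1). The default layout places
one channel pair at the barrier top (±0.15) and two pairs inside the
wells (±0.6, ±0.85), with a sigmoid width of 0.5 so every channel carries
signal over most of the inter-well range.

One design point deserves emphasis because it is easy to get wrong:
channels that are *instantaneous* functions of a reversible equilibrium
diffusion form a time-reversible joint process, whose lagged moments
satisfy $\Gamma(r) = \Gamma(r)^\top$. The population linear Granger
matrix of such a process is exactly symmetric — every true
$G^\circ$ is zero, and no causal ordering exists to recover, whatever the
switch points. A planted ordering therefore requires breaking
reversibility in the observation model. Here each channel reads the
coordinate with a response lag proportional to its distance from the
barrier (`response_lags`, default $10\,|s_i|$ frames): barrier channels
report promptly, well channels sluggishly, the way contacts deeper in a
folding funnel form later in the causal cascade. With these lags the
barrier channels genuinely Granger-cause the well channels, and the
$G^\circ$ ranking recovers the plant across seeds. What this toy does
*not* emulate: real contact distances are not conditionally independent
given one scalar coordinate, real noise is not Gaussian or white, and
real folding is not one-dimensional — so passing tests on the toy shows
the machinery is correct and calibrated, not that any particular protein
folds one way or another.

`generate_mini_trajectory()` builds miniature polypeptide-like chains
(N, H, CA, C, O, CB per residue) purely for geometric featurization
tests; the geometry is deliberately toy-like but non-degenerate (no
collinear backbone triples), and three probe frames plant a textbook
hydrogen bond (0.29 nm, 165°) plus one violation of each criterion
separately.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| MVAR order P | SBC over {1,2,3} | – | ties toward smaller P |
| H-bond distance cutoff | 0.32 | nm | donor–acceptor distance |
| H-bond angle window | [130, 180] | deg | at the hydrogen by default; measuring at the donor is a documented option, as the phrase "acceptor–hydrogen donor angle" is ambiguous |
| TICA lag | 120 | ns | converted to frames via dt |
| p(TP|ξ) bins | 50 | – | between the core states |
| overlap bins | 21 | – | between the F and U minima, reference bin at the global PMF minimum |
| states | 6 | – | equidistant centers between minima |
| median filter | 1 | ns | forced odd in frames |
| error blocks | 5 | – | consecutive, disjoint |
| shuffles | 50 | – | minimum 20 enforced |
| Gromos cutoff | 0.3 | nm | all-atom RMSD, heavy atoms by default |

Distances are in nanometres and angles in degrees throughout; RMSD uses
heavy atoms by default (hydrogens optional).

## Numerical choices and degenerate inputs

* Normalization uses the population variance (divide by T); a two-frame
  channel {0, 2} maps to {−1, +1}. Channels with variance below 1e−12 are
  rejected by name — such channels cannot be scaled meaningfully. Real
  covalent-neighbour distance channels fluctuate enough to pass; they
  simply earn near-zero couplings.
* The singular Yule–Walker system (duplicated channels) errors with a
  rank-deficiency hint instead of returning a pseudo-inverse fit.
* Granger values in (−10⁻⁶, 0) are clipped to 0; worse violations raise.
* Equidistant frames between two state centers go to the lower index;
  Gromos neighbour-count ties go to the lowest frame index; equal trial
  coordinate scores preserve input order.
* All simulators draw from isolated RNG streams derived from a single
  integer seed, so identical seeds give bit-identical outputs and nothing
  touches the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the asymptotic claims at sizes where they are
decidable but cheap: VAR recovery and the Granger limiting values at
$T = 10^5$; moment convergence across $T = 10^3, 10^4, 10^5$; the
diffusive double well at $10^6$ steps (shared across tests); the toy
folder for Granger ranking at $2\times10^5$ frames with 50 shuffled
nulls; calibration of the significance test over 25 white-noise
replicates. The full suite runs in well under a minute on one CPU.

## Known limitations

* Granger couplings are linear: nonlinear dependencies invisible to an
  MVAR model (e.g. transfer-entropy-detectable ones) are out of scope by
  design.
* For exactly time-reversible observations the linear Granger matrix is
  symmetric in population; observed $G^\circ$ asymmetries on equilibrium
  trajectories are finite-sample quantities whose stability must be
  judged by the split-half and shuffle tests the package provides.
* The committor and event statistics assume the median-filtered state
  sequence is a faithful coarse-graining; no Chapman–Kolmogorov or
  implied-timescale validation is attempted (deliberately — the state set
  is interpretive, not a kinetic model).
* The PDB reader handles multi-model PDB only; other formats enter
  through the documented `as_md_trajectory()` adapter contract
  (coordinates in nm plus an atom table).
* Medoid searches subsample states above 2000 frames (deterministically,
  by seed), trading exactness for O(m²) tractability.

## Pipeline

`run_pipeline(pipeline_config(...), workdir)` chains featurize → tica →
validate-rc → states → pathway → granger → report, each stage reading its
upstream artifacts from the working directory and writing delimited-text
outputs plus a provenance sidecar (configuration, seed, input checksums).
Identical configuration and seed give byte-identical outputs; a missing
upstream artifact names the stage that should have produced it. The
`input = "toy"` mode runs the whole chain on the synthetic folder with no
external files.
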