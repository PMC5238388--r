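---
title: "Temporal dihedral cross-correlation analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal dihedral cross-correlation analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcf)
```

## The problem

Functional sites of a protein are often far apart in space yet act in
concert: binding at one residue changes, some nanoseconds later, the
propensity of another residue to bind. Equal-time covariance analyses
(Pearson correlations between dihedral fluctuations, dynamic
cross-correlation maps) see only the instantaneous component of this
coordination. Macromolecular association happens on rotational-diffusion
timescales — tens of nanoseconds — so the question of *when* a fluctuation at
one site is felt at another needs a genuinely temporal observable.

This package works with the time-dependent dihedral cross-correlation
function (TDCF): the normalized two-point correlation between fluctuations of
one dihedral angle and, a lag $\Delta t$ later, another,

$$C_{i,j}(\theta\theta'; \Delta t_l) \;=\;
  \frac{1}{N_l}\sum_{t_1}
  \frac{\delta\theta_i(t_1)\,\delta\theta'_j(t_1+\Delta t_l)}
       {\sqrt{\mathrm{var}(\theta_i)\,\mathrm{var}(\theta'_j)}},
\qquad N_l = N - l,$$

where $\theta, \theta' \in \{\phi, \psi, \chi_1\}$ and
$\delta\theta$ are deviations from the (circular) mean. At $\Delta t = 0$
this is the Pearson coefficient; at positive lags it is generally
*asymmetric* under exchange of the two dihedrals, and that asymmetry is the
operational handle on direction: if perturbations at residue $i$ precede
responses at $j$, the forward curve ($i$ at the earlier time) is the stronger
one.

The frequency-domain summary is the numerical Laplace transform
$F_{i,j}(\theta\theta'; s) = \int_0^{\Delta t_{max}} C(\Delta t)
e^{-s\Delta t}\, d\Delta t$. Its extremum over $s$ measures correlation
strength (a maximum for net-correlated pairs, a minimum for anti-correlated
ones — the sign of $F(s\to 0)$ is the sign of the Pearson coefficient), the
inverse extremum position is a characteristic timescale $\tau = 1/s_{peak}$,
and for large $s$, $|F| \sim s^{-\kappa}$ decays algebraically with
$\kappa \simeq 1$ whenever the equal-time correlation is nonzero (the leading
Watson term of the transform is $C(0)/s$).

## The analytic model

Everything above is validated against a minimal model that is solvable in
closed form: two overdamped, linearly coupled harmonic degrees of freedom,

$$\gamma_i \dot\theta_i = -\omega_i^2\,\theta_i + \alpha'\,\theta_j + \xi_i,
\qquad
\gamma_j \dot\theta_j = -\omega_j^2\,\theta_j + \beta'\,\theta_i + \xi_j,$$

with drift matrix
$A = \bigl(\begin{smallmatrix}-\omega_i^2/\gamma_i & \alpha'/\gamma_i\\
\beta'/\gamma_j & -\omega_j^2/\gamma_j\end{smallmatrix}\bigr)$.
For the stochastic variant, the stationary covariance $\Sigma$ solves the
Lyapunov equation $A\Sigma + \Sigma A^T + D = 0$ (`stationary_covariance()`,
via the Kronecker vectorization identity); the package equally supports the
deterministic-relaxation reading — averaging over an initial-condition
covariance $\Sigma_0$ — through the `sigma0` field of
`oscillator_system()`, since both variants share
$C(\Delta t) \propto [e^{A\Delta t}\Sigma]$ and differ only in which
covariance seeds it. The Laplace transform is the resolvent entry
$[(sI-A)^{-1}\Sigma]$; the package computes the lag covariance by
eigendecomposition of $A$ (complex-safe, with a dense matrix-exponential
fallback for near-defective drifts).

The model reproduces, with pencil and paper, every qualitative feature the
estimator is asked to find: the $s\to 0$ extremum sign tied to the Pearson
sign; exchange asymmetry exactly when $\alpha' \neq \beta'$, growing
monotonically with $|\alpha' - \beta'|$; and the tail dichotomy — exponent 1
when the equal-time cross-covariance is nonzero, exponent 2 when it vanishes
(e.g. a diagonal $\Sigma_0$), read off the resolvent expansion
$(sI-A)^{-1} = I/s + A/s^2 + \dots$

## Estimator choices

**Circular data.** Dihedrals live on $(-180^\circ, 180^\circ]$. The default
`fluctuations()` policy removes the circular mean and wraps each deviation
back to the principal branch (minimal-image deviations) — parameter-free and
exact for the small-amplitude fluctuations typical of folded proteins. For
series that hop branches persistently an `unwrap` policy (cumulative
minimal-image increments, arithmetic centering) is available. The variance in
the TDCF normalization is the plain second moment of the wrapped deviations,
which makes $|C(0)| \le 1$ a Cauchy–Schwarz identity; at positive lags
exceedances of 1 of order $1/N_l$ are possible because the full-series
variance is used, and they are reported, never clipped. A per-window
normalization is available as an option.

**Lag grid.** Every multiple of the frame interval up to a quarter of the
series span by default: beyond that, too few observation pairs remain per lag
for the average to be meaningful. `convergence_check()` recomputes the curve
on trajectory prefixes so saturation with trajectory length can be verified
rather than assumed.

**Frequency grid and quadrature.** 200 log-spaced frequencies spanning
$[1/(2\Delta t_{max}),\ 10/dt]$, bracketing the low-$s$ extremum and the
algebraic tail; trapezoid quadrature on the lag grid with the truncation-bias
bound $|C(\Delta t_{max})|/s$ attached per frequency.

**Tail fitting.** The exponent is the least-squares slope of $\ln|F|$ against
$\ln s$ over the highest usable decade. "Usable" means two things: $|F|$ at
least five times the truncation-bias bound (below that the fit would chase
quadrature noise), and $s \le 0.5/dt$. The second cap is a discretization
constraint: the trapezoid rule's relative error on the kernel grows as
$(s\,dt)^2/12$, and for $s\,dt \gtrsim 1$ the discrete transform flattens
toward $dt\,C(0)/2$ instead of decaying — a fit through that plateau would
report a spurious exponent near zero. On a finite window the fitted slope of
a true $1/(s+a)$ tail sits slightly below 1 (e.g. $\approx 0.96$ over
$s/a \in [10, 100]$); the tests therefore compare the estimator against the
least-squares slope of the closed form on the identical window, not against
the asymptotic exponent.

**Extremum.** Interior maximum for net-correlated pairs, interior minimum for
anti-correlated ones; boundary extrema (monotone curves, common when the peak
sits below the smallest resolvable frequency) are flagged and $\tau$ is then
only a bound. Exact ties resolve to the smallest $s$ — the longest, most
conservative timescale — and are flagged.

## The directional map and the path

For a residue pair, `best_dof_pair()` scans all defined dof pairs
($\phi\phi'$, $\phi\psi'$, ..., $\chi_1\chi_1'$; $\chi_1$ uses the IUPAC
$\gamma$-equivalent atom per residue type and is undefined for Gly/Ala) in
both directions and selects the largest $|F_{ext}|$. The winning direction is
read as "the partner evaluated at the later time is downstream". Cells of the
upper-triangular `build_map()` retain both directions, the full dof-pair
table, and the Pearson coefficient of the winning pair.

**Significance.** No threshold for "correlated" exists in closed form, so the
package uses a block-shuffle null: the same max-statistic recomputed with one
residue's series circularly shifted by random offsets of at least one
correlation time (default 200 shuffles), and the cell is significant when the
observed statistic exceeds the null's 95th percentile (the $(n+1)$-rank order
statistic, the standard finite-sample calibration for surrogate tests). Under
matched conditions (relaxation times 2–6 ns, 1500 ns of data, giving a few
hundred effective samples per series) the empirical false-positive rate sits
at the nominal 5%. A known limitation: when the correlation time approaches a
few percent of the series length (tens of effective samples), the null
becomes mildly anticonservative — the mandated exclusion of short shift
offsets removes precisely the largest null statistics, and the splice
discontinuity weakens the surrogate's slow component. Maps built from short
trajectories of slow systems should be read with that bias in mind.

`build_path()` then walks the map: from the current residue, step to the
spatially closest (smallest mean $C_\alpha$–$C_\alpha$ distance) downstream
residue not yet visited; stop when the downstream set is exhausted, with a
cycle guard at $N_{res}$ steps. Distance ties resolve to the lower residue
index and are flagged. `amplitude_vs_variance()` pairs each significant
cell's strength with the variance of the matching distance
(backbone–backbone pairs with $\mathrm{var}(d_{\alpha\alpha})$,
backbone–sidechain with $\mathrm{var}(d_{\alpha\beta})$,
sidechain–sidechain with $\mathrm{var}(d_{\beta\beta})$): large amplitudes
clustering at small variance is the signature that large positional
fluctuations destroy dihedral correlations.

## Transfer entropy

As an independent directionality check, `direction_by_te()` computes plug-in
histogram transfer entropy in both directions,
$TE(x\to y) = H(y_{next}\mid y_{past}) - H(y_{next}\mid y_{past}, x_{past})$,
with delay-embedded pasts: embedding dimension from the Kennel
false-nearest-neighbour criterion, embedding interval from the delayed-MI
optimum, 8 bins per axis. Two estimator realities shape the defaults. First,
the joint histogram has $bins^{2m+1}$ cells, so the embedding dimension is
capped (default $m \le 2$) — uncapped embeddings on $10^4$-sample series
produce pure-bias estimates whose direction comparison is meaningless.
Second, noise-driven stationary series have no finite embedding dimension, so
the FNN fraction rarely crosses the threshold on such data; the FNN result
and its convergence flag are reported alongside. The plug-in estimator is
nonnegative by construction; a negative reported transfer entropy requires
some bias-subtraction convention, so published negative values cannot be
compared to these numbers directly — the shuffle-bias estimate
(`n_shuffle > 0`) is the package's auditable substitute, and the statistic
that matters for direction is the forward/reverse comparison, which is
bias-balanced.

## The synthetic-data generator

`make_system()` builds whole synthetic "proteins": one stationary linear
(Ornstein–Uhlenbeck) variable per residue/dof, relaxation times of a few ns
(defaults drawn from 2–20 ns; tests that quantify recovery power fix them at
2–6 ns so that 1500 ns of data contains a few hundred effective samples),
stationary amplitudes of 25° — comfortably inside the small-angle regime, so
circular wrapping is inert and the planted linear correlations survive intact
(a `wrap-stress` mode with 80° amplitudes centred near the branch cut
exercises the circular-statistics path instead). Directed couplings are
planted as off-diagonal drift entries (default rate 0.6 / ns, which yields
equal-time correlations of 0.45–0.9 along a chain — strong enough that a
five-residue chain is recovered end-to-end in well over 90% of seeds, weak
enough that direction must genuinely be inferred from the lag structure). A
purely directed topology keeps the drift triangular, hence always stable;
reciprocal topologies are rescaled to stability with a warning. Because
couplings amplify downstream variances, the assembled system is put through a
diagonal similarity transform that pins every stationary standard deviation
back to its target — Pearson correlations, eigenvalues and timescales are
invariant under it, only the amplitudes change.

Residue geometry is a coarse chain-like 3-D curve (consecutive residues are
nearest neighbours, as in a real backbone), plus per-frame isotropic Gaussian
jitter whose amplitude can be tied to coupling status
(`jitter_mode = "by-coupling"`), giving the amplitude-versus-variance
analysis a planted structure to find; $\mathrm{var}(d)$ scales as jitter².

What the generator does *not* emulate: multimodal rotamer hopping, breathing
modes and other non-Markovian kinetics, force-field-specific couplings
between backbone and side chains, or real secondary-structure geometry.
Passing the recovery suites therefore demonstrates that the estimators do
what they claim on stationary, linearly coupled angular dynamics with known
ground truth — not that any particular biological system satisfies those
assumptions.

## Problem sizes and numerical settings

The validation experiments use: $10^6$ Euler–Maruyama steps at $dt = 0.02$ ns
for the tail-exponent measurement (relaxation times 5 and 18 ns, asymmetric
couplings, equal-time correlation ≈ 0.3); eight replicate runs of
$2\times10^5$ steps for estimator-recovery checks, compared at three
Monte-Carlo standard errors; 50 seeds of the five-residue chain (1500 ns at
0.1 ns sampling, 100 shuffles per cell) for path recovery; three ten-residue
independent systems for false-positive control; and twenty seeds for the
transfer-entropy direction check. The Euler–Maruyama step is validated
against the exact stationary law (variance bias $O(dt/\tau) < 1\%$ at the
defaults); simulations initialize from the stationary distribution and still
discard ten slowest relaxation times of burn-in.

## Reading trajectories

`read_structure()`/`read_trajectory()` wrap bio3d's PDB and DCD readers
(coordinates are converted to nm; 1-based contiguous residue indices are kept
alongside author numbering). XTC is not supported — no installed R reader
exists — and pre-extracted per-residue series in the plain-text
`res<idx>_<dof>.tsv` dialect are the equivalent, format-agnostic entry point.
Equilibration is handled either by dropping a configurable leading fraction
(default 5%) or by `backbone_rmsd_burnin()`: moving-window means of the
backbone RMSD after optimal superposition, with the first window after which
the mean never again moves by more than the tolerance; profiles that never
saturate return the trajectory start with an explicit no-equilibration flag.

The Stokes–Einstein utility `rotational_time()` exposes both the rank-1
($\tau = 4\pi\eta R^3/k_BT$) and rank-2 ($3\times$ shorter) conventions,
since experimental reports differ; at 310 K in water ($\eta = 0.69$ mPa s) a
hydrodynamic radius of ~3.5 nm — plausible for a ~110 kDa enzyme — gives a
rank-1 time near 90 ns, the regime in which path timescales become comparable
to partner rotational diffusion.

## Worked example

```{r example, eval = FALSE}
sys <- make_system(5, edges = chain_edges(1:5), tau_ns = 2:6, seed = 1)
dat <- generate_synthetic(sys, length_ns = 1500, dt_ns = 0.1, seed = 2)
map <- build_map(dat$series, max_lag_ns = 30, n_null = 100, seed = 3)
dtab <- distance_table(dat, t(combn(5, 2)), "alpha-alpha")
build_path(map, dtab, start = 1)
```

The numbered scripts under `analysis/` run this workflow end to end on a
ten-residue system (planted chain plus uncoupled controls) and write every
table under `results/`; `scripts/acceptance.R` recomputes the tail-exponent
measurement from scratch.

## Known limitations

* The shuffle-null threshold is anticonservative at tiny effective sample
  counts (correlation time within a factor ~30 of the series length).
* Boundary extrema make $\tau$ a bound, not an estimate; trajectories must be
  long enough that the peak enters the resolvable frequency window.
* The transfer-entropy module is a plug-in histogram estimator by design —
  auditable, but upward-biased; only forward/reverse comparisons and
  shuffle-bias-corrected magnitudes should be interpreted.
* Chi2 and higher side-chain dihedrals, Fourier spectral densities, and
  windowed estimators are out of scope.
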