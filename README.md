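# tdcf — temporal cross-correlation analysis of protein dihedrals

Equal-time covariances (Pearson correlations, DCCM-style maps) show *that*
two protein residues fluctuate together, but not *when*: binding events
propagate between sites over tens of nanoseconds, and that temporal structure
is invisible at zero lag. `tdcf` implements the time-dependent dihedral
cross-correlation function (TDCF) pipeline for MD trajectories:

$$C_{i,j}(\theta\theta';\Delta t_l)=\frac{1}{N_l}\sum_{t_1}
\frac{\delta\theta_i(t_1)\,\delta\theta'_j(t_1+\Delta t_l)}
{\sqrt{\mathrm{var}(\theta_i)\,\mathrm{var}(\theta'_j)}},\qquad N_l=N-l,$$

for backbone ($\phi,\psi$) and side-chain ($\chi_1$) dihedrals, followed by
the numerical Laplace transform $F(s)=\int_0^{\Delta t_{max}}C(\Delta t)\,
e^{-s\Delta t}d\Delta t$. The extremum of $F$ measures correlation strength,
its position gives the timescale $\tau=1/s_{peak}$, and the large-$s$ tail
decays algebraically, $|F|\sim s^{-\kappa}$ with $\kappa\simeq 1$ whenever
the equal-time correlation is nonzero. Because the TDCF is asymmetric under
exchange of the two dihedrals, the stronger direction defines which residue
is *downstream*; scanning all dof pairs for all residue pairs yields a
directional correlation map, and repeatedly stepping to the spatially closest
downstream residue yields the downstream-correlated path.

Every stage is validated against a closed-form model — two overdamped,
linearly coupled harmonic dihedrals with asymmetric couplings
$\alpha' \neq \beta'$ — whose stationary covariance (Lyapunov equation),
lagged correlation ($e^{A\Delta t}\Sigma$) and Laplace transform (resolvent
$[(sI-A)^{-1}\Sigma]$) are exact. The same model powers a synthetic-protein
generator with planted directed coupling networks and known ground truth.
A plug-in histogram transfer-entropy module (false-nearest-neighbour
embedding, delayed-MI interval) provides an independent cross-check of
direction assignments.

## Worked example

A ten-residue synthetic protein with a planted directed chain
`1 -> 2 -> 3 -> 4 -> 5` over the $\phi$ dihedrals (residues 6–10 uncoupled),
1500 ns at 0.1 ns sampling:

```r
library(tdcf)
sys <- make_system(10, edges = chain_edges(1:5), tau_ns = 2:6,
                   jitter_mode = "by-coupling", seed = 2026)
dat <- generate_synthetic(sys, length_ns = 1500, dt_ns = 0.1, seed = 2027)

f1 <- fluctuations(dat$series$res1_phi)
f2 <- fluctuations(dat$series$res2_phi)
curve <- tdcf_estimate(f1, f2, max_lag_ns = 30)   # forward: residue 1 earlier
lap   <- laplace_transform(curve)
laplace_extremum(lap); tdcf_pearson(f1, f2)

map  <- build_map(dat$series, max_lag_ns = 30, n_null = 100, seed = 2027)
dtab <- distance_table(dat, t(combn(10, 2)), "alpha-alpha")
build_path(map, dtab, start = 1)
```

Running the numbered drivers under `analysis/` performs this end to end and
prints, for the head pair of the chain:

```
res1_res2: C(0) = +0.399 | F_ext fwd +2.715 (tau 60.0 ns) rev -0.144 (tau 60.0 ns) | kappa 1.04
res6_res7: C(0) = +0.076 | F_ext fwd +0.260 (tau 11.4 ns) rev +0.129 (tau 2.9 ns) | kappa NA
```

— the planted pair carries an equal-time correlation of 0.40, a forward
Laplace peak twenty times the reverse one (the exchange asymmetry that
encodes direction), and a tail exponent near 1; the uncoupled control pair
sits at the noise level. The map step recovers the planted directionality
(`downstream of residue 1: {2, 3, 4, 5}`, `downstream of residue 6: {}`) and
the transfer-entropy cross-check agrees with the TDCF direction on all four
chain edges, e.g.

```
3-4: m = 2, tau = 2.0 ns, TE 3->4 = 0.067 bits (bias 0.040), TE 4->3 = 0.035 -> i->j [TDCF i->j, agree]
```

In this particular realization the path walks `1 -> 2 -> 3 -> 5`: the `3-4`
cell fell just below the shuffle-null threshold, a reminder that the
significance filter is conservative on single realizations (the multi-seed
recovery rate of the full chain exceeds 90%; see the test suite).

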