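---
title: "Frequency-specific small-worldness of envelope networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-specific small-worldness of envelope networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swpnet)
```

This vignette is the package's account of the science it implements: the
model at each stage, the assumptions behind it, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, and
the numerical conventions adopted where the methodology is genuinely open.
It states no empirical result that the test suite does not itself compute.

## 1. The analysis chain

Given S subjects' ROI signals $X_i(t)$ ($i = 1..N$ nodes, sampling rate
$f_s$), the pipeline estimates, per carrier frequency $f$ and subject, a
weighted functional-connectivity graph, then sweeps graph density and asks
where along the frequency axis the networks are small-world.

**Spectra.** Each signal is convolved (frequency-domain multiplication,
zero-padded to the next power of two) with a generalized Morse wavelet
scaled to each carrier. The Morse window on positive frequencies is
$\omega^\beta e^{-\omega^\gamma}$; it is *strictly analytic* — identically
zero at DC and negative frequencies — which is why this family is preferred
over, say, Morlet approximations for envelope work: the complex coefficient
$W_i(f, t)$ has a well-defined instantaneous amplitude and phase by
construction. We normalize the peak frequency response to 1 ("bandpass
normalization"), so a unit complex exponential at the carrier yields a unit
envelope (a real cosine of amplitude $a$ yields $a/2$, its analytic
positive-frequency content).

* `gamma = 3` selects the symmetric ("Airy") members, the standard
  recommendation for exploratory time-frequency analysis.
* `beta = 25/3` makes the time-bandwidth product $P=\sqrt{\beta\gamma}=5$,
  about five oscillation cycles under the envelope — a conventional
  resolution compromise. The methodology this implements does not pin an
  exact $(\beta, \gamma)$, so both are exposed (`morse_params()`); results
  in the test suite are checked to vary *continuously* in $\beta$.
* The carrier grid defaults to $2^{0.5}, 2^{0.75}, \dots, 2^{6}$ Hz — 23
  quarter-octave carriers from ≈1.414 to 64 Hz, covering delta through
  gamma.
* Edge handling: samples within one wavelet half-support
  ($P/f \cdot f_s$ samples) of either end are *masked*, not tapered;
  signals shorter than four wavelet supports at a carrier are rejected
  with an error naming that carrier.

**Connectivity.** Zero-lag coupling between source estimates is dominated
by field spread, so before correlating envelopes each pair is
orthogonalized: $Y_{\perp X}(t) = \Im\{Y(t) X^*(t)/|X(t)|\}$, the
quadrature component of $Y$ relative to $X$. Any instantaneous real mixture
of $X$ maps to exactly zero (`orthogonalize()` tests assert this), so what
survives is coupling with a phase lag or envelope covariation. Log power
($\log|\cdot|^2$, floored at machine epsilon times the peak envelope) is
Pearson-correlated in both directions ($X$ vs $Y_{\perp X}$, $Y$ vs
$X_{\perp Y}$), each $r$ clipped to $1 - 10^{-12}$ before the Fisher
transform, and the two z values averaged — making the edge weight symmetric
by construction.

*Rectification.* Whether negative envelope correlations should be kept,
absolute-valued or zeroed is not settled in this literature; the package
zeroes them by default (`rectify_negative = TRUE`) because the weighted
clustering and inverse-weight path machinery require non-negative weights.
This inflates the mean of null edges slightly (a half-normal effect) —
visible in the synthetic tests as a small positive off-backbone mean — but
affects both tails of every contrast equally.

**Consistency thresholding.** For each carrier, each edge's coefficient of
variation across subjects (sample sd / mean) ranks its reliability; at
density $d\%$ the $\mathrm{round}(d/100 \cdot N(N-1)/2)$ lowest-CV edges
are kept (round half away from zero), producing one mask per (carrier,
density) shared by *all* subjects — equally sparse graphs, comparable
metric values — and nested masks across the sweep. Conventions the source
methodology leaves open, fixed here deterministically: ties break by
descending mean weight, then lexicographic edge index; zero-mean edges
(CV undefined) rank last.

**Small-world metrics.** On each thresholded weighted graph:

* Onnela clustering: $\hat w = w/\max w$;
  $C_i = \frac{1}{k_i(k_i-1)}\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$,
  zero for degree < 2; invariant to global weight rescaling.
* Path length: edge length $1/w$, Dijkstra all-pairs; $L$ = mean finite
  off-diagonal distance, with the unreachable fraction reported.
* Lattice equivalent: same $N$, $E$ and weight multiset arranged on a ring,
  shortest ring distances filled first, strongest weights most local —
  deterministic, maximizing local clustering.
* Random equivalent: uniformly random simple topology with the same $N$ and
  $E$, weights randomly permuted onto edges; metrics averaged over
  `n_reps = 10` seeded realizations (how many realizations the original
  analysis averaged is unstated; 10 keeps the Monte-Carlo error well below
  the effects of interest at these graph sizes).
* $\Delta C = (C_{latt}-C_{obs})/(C_{latt}-C_{rand})$,
  $\Delta L = (L_{obs}-L_{rand})/(L_{latt}-L_{rand})$, both clipped to
  $[0,1]$; $\mathrm{SWP} = 1-\sqrt{(\Delta C^2+\Delta L^2)/2} \in [0,1]$,
  with SWP > 0.6 the conventional small-world regimen; and
  $\sigma = (C_{obs}/C_{rand})/(L_{obs}/L_{rand})$ (> 1 = small world),
  computed from the same null draws.

Two numerical conventions deserve emphasis. First, the ΔL numerator: the
defining publication's formula is followed ($L_{obs} - L_{rand}$); the
package emits a one-time message stating the convention, because a
dimensionally inconsistent variant (a clustering term inside the
path-length ratio) circulates in print. Second, degenerate graphs: when the
lattice and random nulls coincide (near-empty graphs — no triangles, no
meaningful paths), the corresponding deviation is defined as 0 *with a
warning*, which pushes SWP toward 1. Such cells almost always also exceed
the 5%-unreachable-pairs bound and are flagged `unreliable` in the curve
set. **Aggregate comparisons should honor those flags**: in the package's
own acceptance test the planted-band-vs-noise-band contrast averages SWP
over non-flagged cells, because the degenerate SWP = 1 cells carry no
topological information and their inclusion makes low-density averages a
coin flip on the noise carrier.

**Statistics.**

* `rm_anova()`: one-way within-subject F with Mauchly's W (orthonormal
  contrasts) and Greenhouse–Geisser $\varepsilon$
  ($\mathrm{tr}(S_c)^2 / [(k-1)\,\mathrm{tr}(S_c^2)]$, bounded in
  $[1/(k-1), 1]$); the corrected p uses $(\varepsilon(k-1),
  \varepsilon(k-1)(n-1))$ degrees of freedom. With 33 subjects and 23
  carriers the uncorrected df are (22, 704).
* `tukey_hsd_within()`: studentized-range p per carrier pair from the
  within-subject error MS — the repeated-measures analogue of Tukey HSD.
  The companion Bonferroni display threshold for 23 carriers at
  $\alpha = 0.05$ is $0.05/23 = 0.0022$ (4-decimal display; exact value
  kept internally). Correcting for all 253 pairs instead would give
  0.0002 — derivable via `bonferroni_threshold(0.05, 253)` but not the
  default convention.
* `fda_curve_test()`: the whole metric-vs-density curve is one functional
  observation. The exact basis/penalty used by prior functional-data
  treatments of graph metrics is not printed in the methodology this
  follows, so the statistic here is a documented stand-in: the
  grid-weighted integral (normalized trapezoid weights, hence invariance
  under affine grid reindexing) of the squared pointwise t statistic, with
  `stat = "max_t"` exposed as an alternative. The null is permutation-based
  — per-subject sign flips for paired designs, label shuffles otherwise —
  and $p = (1 + \#\{T^{null} \ge T^{obs}\})/(1 + n_{perm})$, which includes
  the identity and can never be 0. Zero-variance grid points are dropped
  with a notice (identical curve sets therefore give statistic 0, p = 1).
  Default `n_perm = 10000`; tests use fewer.
* `prepost_density_ttests()`: paired t per density with significance at
  `alpha/m`; `m` is the caller's multiplicity convention (the display
  convention above corrects for the 23 carriers, not the 253 pairs or the
  density count).

Type-I calibration of both permutation and t machinery is asserted in the
test suite (empirical rejection in [0.03, 0.07] at nominal 0.05 over 1000
null replicates).

## 2. The synthetic world

No recordings ship with this package, so validation rests on a generator
whose statistical structure matches what the envelope-connectivity model
assumes:

* **Backbone**: a known graph (default Watts–Strogatz, mean degree 4,
  rewiring 0.1 — genuinely small-world at planted size) is the ground
  truth to recover.
* **Envelopes**: rectified low-pass (~1 Hz Gaussian-kernel cutoff) Gaussian
  processes — the slow power co-fluctuations envelope correlation is
  designed to detect. One latent envelope per backbone *edge*; node $i$
  mixes its private envelope with the mean of its incident edge latents,
  weighted $(1-\rho) : \rho$. Adjacent nodes therefore share envelope
  variance; non-adjacent nodes (even with common neighbors) share none.
  Planted edge correlation grows monotonically with $\rho$.
* **Carriers**: each node's oscillation is its envelope times a cosine at
  the coupling frequency with an i.i.d. random phase — so zero-lag
  coherence carries none of the planted structure, and the coupling
  *survives orthogonalization* (the property that makes the fixture a fair
  test of the connectivity stage).
* **Background**: $1/f^a$ noise (spectrally shaped white noise, default
  $a = 1$), unit RMS; the oscillation is scaled to RMS = `snr`.
* **Defaults**: 12 subjects × 20 nodes, $f_s = 256$ Hz, 60 s,
  $\rho = 0.8$, snr = 2 — the conditions under which the package's
  recovery tests are stated. The source recordings' SNR and envelope
  autocorrelation are uncharacterized, so these are conventional choices
  for a clean electrophysiological band, chosen once and not revisited.
  Subject $s$ seeds its stream at `seed + s`, making fixtures stable.

What the generator does **not** emulate: volume conduction with a realistic
head model (orthogonalization is validated against instantaneous *mixtures*
instead), non-stationarity, 50/60 Hz line noise, artifacts, inter-subject
topology variability (all subjects share one backbone; only noise differs),
and realistic 384-node atlas dimensionality (tests run at 8–30 nodes). A
green recovery test therefore establishes that the pipeline detects planted
envelope structure at the right carrier and ranks its small-worldness above
a noise carrier — not that any particular empirical claim about human
resting-state data is reproduced.

## 3. Design choices that were genuinely open

* **Node strength** is the mean of the off-diagonal column entries
  (`strength.mode` also offers `mean_incl_diag` and `sum`): "mean of the
  adjacency columns" is ambiguous about the structurally zero diagonal, and
  the off-diagonal mean is the interpretation under which a two-node graph
  of weight $w$ has strength $w$.
* **CV** uses the sample (n−1) standard deviation.
* **Envelope correlation at full temporal resolution** over the valid mask
  (no binning/decimation); binning conventions vary across envelope-FC
  studies and none is canonical.
* **Random-null count** `n_reps = 10`, seeded per cell from the master seed
  and the cell's data (not its array position), so subject reordering and
  parallel execution cannot change results.
* **I/O is delimited text + JSON** (per-subject CSV, edge-list TSV,
  long-format curve CSV, checksum manifest); the environment this package
  targets has no HDF5 R binding, and at the scales involved text round-trips
  are exact to 15 significant digits (asserted in tests).

## 4. Known limitations

* SWP on very sparse or disconnected graphs is reported but flagged
  (`unreliable`, `edgeless`); treat flagged cells as missing in aggregates.
* σ inherits its well-known density dependence; the suite demonstrates
  (on matched Watts–Strogatz families) that σ's decay across density
  exceeds SWP's relative change, which is the reason SWP is the headline
  index here.
* `rm_anova()` requires complete data and $n - 1 > k - 1$ subjects for a
  defined Mauchly test (otherwise W is NA and only the GG correction is
  reported).
* The FDA statistic is a principled stand-in, not a reimplementation of any
  specific published spline-basis pipeline; with `n_perm` permutations the
  smallest attainable p is $1/(n_{perm}+1)$.
* Runtime scales as $S \times N^2 \times$ carriers for connectivity and as
  subjects × carriers × densities × (`n_reps` + 2) Dijkstra/clustering
  evaluations for the curves; the 384-node, 100-density configuration of
  the source methodology is hours of CPU, which is why tests and examples
  run scaled-down configurations of the same code path.
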