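---
title: "Methods: pairwise maximum-entropy models and energy landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise maximum-entropy models and energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model, estimators, algorithms and numerical
choices behind `memland`, including the decisions made where more than one
reasonable implementation exists.

## The model

Coarse-grained brain activity is reduced to a binary vector
$\sigma^t = (\sigma_1^t, \dots, \sigma_N^t)$ per time point: each of $N$
functional clusters is "on" or "off".  The pairwise maximum-entropy model
(MEM) is the distribution over the $2^N$ activity patterns that matches the
observed activation rates $\langle\sigma_i\rangle$ and coactivation rates
$\langle\sigma_i\sigma_j\rangle$ while maximizing entropy — i.e. assuming
nothing beyond first- and second-order statistics.  It is the Boltzmann
distribution of the Ising model:

$$P(\sigma) = \frac{1}{Z} e^{-E(\sigma)/T}, \qquad
E(\sigma) = -\sum_i h_i \sigma_i - \frac{1}{2}\sum_{i\neq j} J_{ij}\sigma_i\sigma_j,$$

with per-region activation biases $h_i$, symmetric zero-diagonal couplings
$J_{ij}$, and a temperature $T$ (fitted data live at $T = 1$; $T$ is a
global scale used for the thermodynamic analyses).  Key assumptions: the
data are binarized meaningfully (see binarization below), time samples are
treated as exchangeable draws for fitting (temporal order is used only by
the dynamics analyses), and interactions beyond second order are absent
from the model by construction — their importance is *measured* afterwards
via the multi-information fraction rather than assumed away silently.

### State conventions

Both common encodings are first-class: spins $\sigma_i \in \{-1,+1\}$
(`"pm1"`) and occupations $\sigma_i \in \{0,1\}$ (`"01"`).  The affine map
$s = 2\sigma - 1$ induces the exact reparameterization
$J^{01} = 4J^{\pm}$, $h^{01}_i = 2h^{\pm}_i - 2\sum_j J^{\pm}_{ij}$
(`convert_convention()`), under which the distribution — and hence every
distribution-level quantity (state probabilities, entropies, specific
heat) — is invariant; magnetization-based quantities rescale accordingly
($\chi^{01} = \chi^{\pm}/4$).  Fitting defaults to `"pm1"`; thermal
simulations are typically run in `"01"`, where the low-temperature regime
shows the characteristic alternation of brainwide activation and silence.
One subtlety worth knowing: *virtual resection is not
convention-equivariant*.  Zeroing a region's couplings in the `"01"`
parameterization is a different physical perturbation than zeroing them in
`"pm1"`, because the conversion folds couplings into the fields.  In the
degenerate case of a model converted from a zero-field `"pm1"` model, the
`"01"` resection leaves the energy statistics exactly unchanged.  The
package performs the resection in whatever convention the model is
expressed in; choose the convention deliberately.

### State indexing

All enumeration-based functions order states by the integer index whose
bit $j-1$ holds cluster $j$ (cluster 1 = least significant bit).  Indices
are 0-based and appear as such in all exports, so state identities are
reproducible across functions, files and sessions.

## Fitting

### Exact likelihood gradient (N ≤ 20, default up to 15)

Maximum-likelihood fitting of an exponential family reduces to moment
matching.  `fit_mem(method = "exact")` iterates

$$h_i \leftarrow h_i + \epsilon\,(\langle\sigma_i\rangle_{\rm data} -
  \langle\sigma_i\rangle_{\rm model}), \qquad
  J_{ij} \leftarrow J_{ij} + \epsilon\,(\langle\sigma_i\sigma_j\rangle_{\rm data} -
  \langle\sigma_i\sigma_j\rangle_{\rm model}),$$

with model moments computed exactly by enumeration (log-sum-exp
normalization for stability).  Convergence is declared when the maximum
absolute moment discrepancy falls below `tolerance` (default $10^{-4}$; at
convergence the fitted model reproduces the data moments to that
precision, which is also the fixed-point property the tests assert).  The
learning rate starts at 0.1 and adapts: grown by 2% per improving step
(capped at 10× the initial rate), cut to 70% on oscillation.  These values
are not critical — they trade iterations for robustness — and the
defaults converge in a few hundred iterations for typical $N \le 12$
problems.

Moments on the boundary of the attainable set (a cluster constant over
time, or two clusters perfectly correlated) correspond to infinite
parameters; they are rejected with an error naming the offending cluster
or pair and suggesting a lower binarization threshold or cluster merging,
rather than silently regularized.

### Pseudo-likelihood (any N)

For larger systems the likelihood gradient is intractable, and the model
is fitted by maximizing the product of single-unit conditional likelihoods
$\prod_t\prod_i \tilde P(\sigma_i^t \mid \sigma_{\setminus i}^t)$, a
consistent estimator as the number of time samples grows.  The conditional
mean given the local field $f_i = h_i + \sum_j J_{ij}\sigma_j$ is
$\tanh(f_i)$ for spins and $\mathrm{logit}^{-1}(f_i)$ for occupations; the
implementation derives and uses the correct form for each convention (the
two routes are tested against each other through `convert_convention()`).
Updates use the same moment-discrepancy form as the exact fit, with the
model-side statistics replaced by conditional ones.  Symmetry of $J$ is
enforced throughout by averaging the two directed gradient contributions —
equivalent to symmetrizing the directed estimates, but applied each step
so the iterate never leaves the symmetric manifold.  Since the objective
depends on the data only through state counts, time points are collapsed
to unique states with weights, making each iteration $O(\min(T, 2^N)
N^2)$.

The `"auto"` method switches from exact to pseudo-likelihood above
$N = 15$ (user-overridable), the scale where full enumeration starts to
become expensive.

## Preprocessing

* **Spatial parcellation**: k-means on neuron x/y/z positions
  (`stats::kmeans`, 10 random restarts, best within-cluster sum of
  squares, fixed seed).  Random restarts rather than a k-means++ seeding
  are used; with the well-separated blob geometry this package's synthetic
  data produce — and with 10 restarts — initialization is not a practical
  concern.
* **Functional clustering**: agglomerative clustering of ROI traces with
  average linkage on $1 - $ Pearson correlation.  Correlation (rather than
  raw covariance) is used so that ROI amplitude does not dominate the
  grouping; the partition is then invariant to per-ROI rescaling, which
  the tests assert.
* **Binarization**: each cluster trace is z-scored over time; samples
  strictly above the threshold $Z$ are "on".  The strict comparison makes
  the $Z = 0$ case unambiguous and reproducible.  Raising $Z$ can only
  lower on-rates (a tested invariant).  Multi-recording data are handled
  by per-recording z-scoring and binarization followed by concatenation of
  rasters along the time axis (`concat_rasters()`); no cross-recording
  normalization is applied beyond that.

## Evaluating the fit

### Multi-information

With $S_1$ the entropy of the independent model built from empirical
marginals, $S_N$ the plug-in entropy of the empirical state distribution
and $S_2$ the entropy of the fitted pairwise model, the total correlation
is $I_N = S_1 - S_N$ and the pairwise model accounts for a fraction
$r = I_2/I_N$ with $I_2 = S_1 - S_2$.  Entropies are computed in nats and
reported in bits.  Two estimator caveats are handled explicitly rather
than ignored:

* The plug-in $S_N$ is biased downward at small $T$; a warning fires when
  $T < 10 \cdot 2^N$.
* Because the plug-in $S_N$ never exceeds the plug-in $S_1$, sampling
  noise alone yields a small positive $I_N$ even for independent data, of
  expected magnitude $(K - 1 - N)/(2T)$ nats (the Miller–Madow bias, $K$ =
  number of observed distinct states).  $r$ is reported only when $I_N$
  exceeds twice this floor; otherwise it is flagged undefined.  This makes
  "no detectable correlation" an explicit outcome instead of a huge or
  nonsensical ratio.

### Structure–function coupling

Fitted couplings are compared with a structural (fiber-count-like) matrix
over the off-diagonal upper triangle: Pearson and Spearman correlations
(both reported, since the choice is not canonical), and ROC/AUC treating
the coupling as a classifier score for the presence of a structural edge,
with edges defined at fractions of the maximum structural weight (default
operating points 1% and 30%).  AUC uses the Mann–Whitney rank-sum
identity — exact and tie-robust, with no curve integration error.  Scores
can be signed couplings or magnitudes; the synthetic generator ties the
structural matrix to $|J|$, so pipeline defaults use `score = "absJ"`
there.  The resolution scan (`scan_resolutions()`) repeats the whole
preprocessing–fitting–evaluation chain over a grid of cluster numbers and
thresholds, aggregating the structural matrix to each resolution by
summing fiber counts between member ROIs' (majority-vote) regions, and
reports the maximizing grid point.

## Energy landscape

Neighbors are states at Hamming distance 1.  A state is a **local
minimum** iff its energy is *strictly* below all $N$ neighbors'.
**Basins** are computed by steepest descent — repeatedly move to the
lowest-energy neighbor until a minimum is reached — which partitions all
$2^N$ states.  Deterministic tie rules: among equally steep neighbors, the
smallest state index is taken; a state with an equal-energy neighbor and
no lower one is not a minimum, and such plateau states are assigned to the
basin of the smallest-index equal-energy neighbor already resolved
(energy-then-index processing order), falling back to the deepest minimum.
One practical note: ties are detected on computed floating-point energies,
so fixtures constructed to have *exactly* tied energies may resolve on
rounding order before the tie rule applies; with continuously distributed
parameters ties have measure zero and the point is moot.

**Saddles and barriers.**  The saddle energy of a pair of minima is
defined by deleting states in order of decreasing energy (ties: larger
index first) until the pair disconnects; the last deleted state is the
saddle.  The implementation runs the exactly equivalent reverse process:
states are *added* in increasing energy order under a union-find, and the
energy at which two minima's components merge is recorded — the minimax
connection energy over all Hamming paths.  Tests verify this equivalence
against an independent minimax-path oracle (maximum edge weight on the
minimum spanning tree of the Hamming graph with edge weight
$\max(E_u, E_v)$).  The asymmetric barrier from minimum $a$ toward $b$ is
$E_{\rm saddle}(a,b) - E_a$; the symmetric barrier is the smaller of the
two.  Merge events also yield the disconnectivity tree (exported as nested
JSON for dendrogram plotting).  Landscapes are always built at $T = 1$:
temperature rescales probabilities, not energies.

## Dynamics

`mcmc_walk()` runs single-flip Metropolis–Hastings: propose one of the $N$
neighbors uniformly, accept with probability
$\min[1, e^{(E(\sigma)-E(\sigma'))/T}]$.  The kernel is compiled (Rcpp),
maintains local fields and energy incrementally ($O(N)$ per step), uses
R's RNG, and draws in a fixed documented order (site, then acceptance
uniform, always both), so chains are bit-reproducible for a given seed.
The default burn-in is 30 000 steps.  Transition counting never thins the
chain — thinning would distort dwell times — while moment estimation uses
thinned samples.

Basin-level statistics count a transition whenever the basin label
changes; dwell times are run lengths; transition probabilities are
reported both row-normalized (out of a basin) and column-normalized (into
a basin), with empty rows/columns flagged rather than normalized by zero.
Empirical and simulated transition counts are compared after rescaling the
simulated total to the empirical total, by linear regression over
off-diagonal pairs; fewer than three active pairs flags the regression
unreliable.  The dwell-time/basin-size relation is summarized by
regressing log mean dwell on basin size.

## Thermodynamics and virtual resection

Specific heat and susceptibility follow the fluctuation–dissipation
relations $C = (\langle E^2\rangle - \langle E\rangle^2)/T^2$ and
$\chi = (\langle M^2\rangle - \langle M\rangle^2)/T$ with
$M = \sum_i \sigma_i$ (unnormalized; divide by $N$ for per-region units).
Two engines agree within Monte-Carlo error (a tested property):

* `thermo_exact()` — enumeration under $P \propto e^{-E/T}$ (N ≤ 20);
* `annealed_sweep()` — a Metropolis chain per temperature on a strictly
  descending grid, each chain seeded with the final state of the previous
  (warmer) one.  Production-scale defaults are $10^6$ steps per
  temperature after 30 000 thermalization steps, retaining every 500th;
  the `scale` argument shrinks all three proportionally (the pipeline
  default is `scale = 0.1`, and the test suite uses grids and chain
  lengths sized so the whole suite runs in well under a minute — e.g.
  $2\times10^5$-step sweeps at $N = 8$).  Monte-Carlo standard errors for
  $C$ and $\chi$ come from the fourth central moment with an AR(1)
  effective-sample-size correction estimated from the lag-1
  autocorrelation of the thinned series.

The default grid is $T = 2$ down to $0.05$ in steps of $0.05$; $T = 0$ is
excluded (acceptance degenerates).  `locate_transition()` takes the
critical temperature as the grid argmax of $C$ with a 3-point quadratic
refinement, and the FWHM from linearly interpolated half-maximum
crossings; a peak on the grid edge or a crossing outside the grid is
flagged, not extrapolated.

**Virtual resection** zeroes one region's couplings.  The resected region
is excluded from the $E$ and $M$ observables: a fully decoupled unit with
nonzero field only adds an independent two-level (Schottky) background to
$C$ that is pure bias when comparing resections across regions.
Equivalently, the curves are those of the reduced $(N-1)$-unit model.
The per-region shift $\Delta T_c$ (and $\Delta C_{\rm peak}$,
$\Delta$FWHM) is taken against the intact model's curve on the same grid
and engine, and `resection_scan()` relates the shifts to the regions'
coupling strengths (row sums of $J$).

## Synthetic data: what it emulates and what it does not

`make_ground_truth()` draws couplings as Gaussian weights on an
Erdős–Rényi support (default density 0.4, scale 0.3), giving a mixture of
positive/negative couplings and of strong/weak regions — contrast that the
resection analysis needs.  Fields are uniform in $[-1, 0]$ so the all-off
state dominates, mirroring sparse activation.  The structural matrix is
$a(|J| + \varepsilon)$ clipped at zero with symmetric Gaussian noise
$\varepsilon$ (sd `structure_noise`, in coupling units; 0 gives exact
proportionality, making AUC = 1 a provable extreme).  The file-based demo
pipeline uses a denser, stronger default (density 0.6, scale 0.45) so that
the fitted $N = 8$ landscape typically has several attractors and the
basin-transition analyses are exercised meaningfully.

`states_to_traces()` emulates recordings as two-level step signals (region
off/on) plus white Gaussian noise of sd $1/\mathrm{SNR}$, with neurons in
well-separated Gaussian blobs per region.  Because the z-scored off level
is always negative and the on level positive (for any on-rate), a
threshold of $Z = 0$ recovers the generating states with error rate
vanishing as SNR grows — the round-trip property the preprocessing tests
rely on.  *Not* emulated: calcium indicator kinetics (rise/decay),
bleaching, motion artifacts, overlapping or irregular anatomy, per-fish
variability.  Passing tests therefore certify the correctness of the
algorithms and estimators, and the internal consistency of the pipeline —
not the adequacy of binarized pairwise modeling for any particular real
recording.

All stochastic operations take an explicit integer seed and restore the
caller's RNG state; no function mutates the global stream.

## Pipeline and interface

The analysis is also exposed as a file-based pipeline
(`run_stage()`/`validate_config()`): JSON config with strict unknown-key
rejection and batched error reporting, per-stage CSV/JSON outputs under
`out_dir/<stage>/`, and a `manifest.json` per stage recording every
parameter actually used (defaults included), input checksums and the
package version.  Numerics are serialized at 17 significant digits, so
identical configurations and seeds give byte-identical outputs.  A thin
CLI wrapper lives at `inst/cli/memland.R`; equivalently, every stage is an
ordinary exported function.

## Known limitations

* Enumeration-based operations scale as $O(2^N)$ in memory and time;
  $N \le 20$ is a hard cap and $N \lesssim 14$ the comfortable range.  No
  approximate landscape exploration is provided for larger systems.
* No L1/L2-regularized inverse Ising, mean-field/TAP inversions, or
  higher-order (triplet) models.
* The plug-in entropy estimator is used deliberately (with the bias
  handling above); no coverage-adjusted entropy estimation is attempted.
* The union-find saddle search is exact but quadratic-ish in pathological
  tie structures; for the continuous energies of fitted models it runs in
  near-linear time in $2^N$.
* Basin assignment of exact-tie plateaus depends on floating-point
  evaluation order before the documented tie rule (see above); this can
  matter only for hand-constructed degenerate fixtures.
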