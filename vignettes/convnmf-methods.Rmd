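---
title: "Methods: penalized convolutional NMF for sequence discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized convolutional NMF for sequence discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A nonnegative data matrix $X$ ($N$ channels $\times$ $T$ timebins —
spike counts, calcium traces, spectrogram magnitudes) is approximated
as a sum of $K$ convolutions

$$\tilde{X}_{nt} \;=\; \sum_{k=1}^{K}\sum_{\ell=0}^{L-1}
W_{nk\ell}\,H_{k,t-\ell},$$

where each exemplar $w_k$ ($N \times L$) stores which channels are
active at which lag within a repeated motif, and the loadings row
$h_k$ stores when and how strongly that motif occurs.  With $L = 1$
the model reduces to classical NMF.  Plain convolutional NMF
reconstructs sequence data well but, when $K$ exceeds the true number
of motifs, splits or duplicates them in unpredictable ways: the same
instance explained twice, a motif cut into pieces, or duplicate
exemplars covering different instances.

The cross-orthogonality ("x-ortho") penalty addresses all three
redundancy modes with a single term,

$$\mathcal{R} \;=\; \lambda\,
\big\lVert (W \circledast^{\top} X)\, S\, H^{\top}
\big\rVert_{1,\,i\neq j},$$

where $(W \circledast^{\top} X)_{kt}=\sum_{\ell,n}W_{nk\ell}X_{n,t+\ell}$
is each factor's matched-filter overlap with the *data* (not the
reconstruction), $S$ is a banded smoothing matrix (moving sum of width
$2L-1$, never materialized — each row is boxcar-summed in $O(T)$), and
the seminorm sums absolute values off the diagonal.  A factor that
overlaps the data where another factor is loaded raises the penalty,
so factors compete to explain each feature and surplus factors are
driven to zero amplitude.

Minimization uses multiplicative updates.  Each iteration performs:
update $H$; shift each factor so its exemplar's lag-wise center of
mass sits at lag $\lfloor L/2\rfloor$ (loadings shifted oppositely;
zero-padded, so the reconstruction is unchanged except within $L$ bins
of the recording edges); renormalize so rows of $H$ have unit norm;
update $W$.  A final $H$-then-$W$ update with all penalties off
restores loading peaks that the penalty slightly suppresses within
$2L$ bins of neighboring sequences.

## Numerical choices

**Initialization.** $W \sim U(0, \max X)$ and
$H \sim U(0, \max X)/\sqrt{T/3}$ under the run seed.  The
initialization scale matters more than is obvious: if the initial
reconstruction sits far *below* the data scale, the reconstruction
term in every multiplicative denominator is negligible, the penalty
term dominates, and all factors shrink geometrically to zero before
any factor specializes — the model collapses for moderate $\lambda$.
Starting at (or above) the data amplitude keeps the
reconstruction-error term dominant through the early iterations.  An
initialization proportional to $\mathrm{mean}(X)/\sqrt{KL}$ was tried
first and exhibits exactly this collapse on sparse sequence data.

**Stabilizer.** Every update denominator carries
$\varepsilon = \max(X)\cdot 10^{-10}$, which avoids $0/0$ without
displacing fixed points.

**Stopping.** `fit_config(tol =)` stops when the relative change of
the total cost, averaged over the last five iterations, falls below
`tol` (default $10^{-6}$).  Caveat: under a strong penalty the total
cost can plateau *transiently* while factor competition is still
resolving (the amplitudes of tied factors evolve slowly at nearly
constant cost), and a cost-based stop can freeze that intermediate
state.  All model-selection protocols in this package therefore run a
fixed iteration budget (`tol = 0`), mirroring the fixed 1000-iteration
regime the method was characterized in; the tolerance is a convenience
for interactive use.

**Cost monotonicity.** The multiplicative updates alone are
non-increasing in the objective, but the interleaved centering step
(integer shifts with zero padding) can raise the cost by a small
amount (empirically $\lesssim 10^{-3}$ of the total, occasionally,
usually within the first tens of iterations).  This is the price of
keeping exemplars centered, and the tests treat cost trajectories as
non-increasing up to that allowance.

**Empty factors.** Suppressed factors end with amplitudes many orders
of magnitude below live ones (relative reconstruction power $10^{-12}$
or smaller) but not always exactly zero, and the significance test
statistic (skewness) is scale-invariant, so a vanishing imprint of a
sequence would still register.  `factor_significance()` therefore
treats factors whose per-factor reconstruction power is below
`empty_tol` ($10^{-6}$ by default) times the strongest factor's power
as empty — reported non-significant without testing.  The observed gap
between live and suppressed factors makes the threshold's exact value
uncritical.

## Held-out significance of factors

The final 25% of timebins is reserved before fitting (a contiguous
split, so no sequence instance straddles the boundary; the fraction is
a choice, not a sensitive one).  For each factor, the overlap trace
with the held-out block is computed and its bias-corrected sample
skewness taken: a factor whose motif genuinely recurs overlaps
strongly at a few times and weakly elsewhere, giving a right-skewed
trace.  Null factors are built by circularly shifting each channel's
lag profile within the exemplar by an independent uniform integer in
$[0, L)$, which preserves per-channel content but destroys the
cross-channel temporal pattern.  A factor is significant when its
skewness exceeds the Bonferroni-corrected $(1-\alpha/K)$ quantile of
its null skews; the default $n_{\mathrm{null}} = \lceil 5K/\alpha\rceil$
per factor makes that extreme quantile estimable.

## Choosing the penalty weight and the number of factors

`lambda_sweep()` fits across a logarithmic grid of $\lambda$.  The
reconstruction cost rises and the x-ortho cost falls with $\lambda$;
after min–max normalization of both mean curves, their crossing point
$\lambda_0$ is located by log-linear interpolation.  Weights between
$2\lambda_0$ and $5\lambda_0$ recover the correct number of sequences
across noise conditions; `recommended` is $3\lambda_0$, the midpoint
of that band in log space.

`select_k()` offers a penalty-free alternative: for each candidate
$K$, several unpenalized fits are run from different seeds and their
pairwise dissimilarity
$$\mathrm{diss}(F_1,F_2)=\frac{1}{2K}\Big(2K-\sum_j\max_k C_{jk}
-\sum_k\max_j C_{jk}\Big)$$
computed from the cross-correlation matrix $C$ of *per-factor
reconstructions* (working with reconstructions removes the temporal
degeneracy of convolutional factors — shifting $h_k$ against $w_k$
leaves $\tilde{X}_k$ unchanged).  diss is 0 when factors match
one-to-one up to permutation and 1 when nothing matches; the $K$
minimizing the median diss is selected.  Factors with an identically
zero reconstruction contribute zero correlation, i.e. count as
maximally dissimilar.  Unpenalized fits are used (a `penalized`
override exists) since stability selection is the alternative to
penalization.

## Sequenciness

Column-shuffling a data matrix destroys temporal sequences but leaves
synchronous (rank-one) structure learnable; shuffling each row by its
own permutation destroys both.  With $P$ the percent power explained
by an unpenalized fit,
$$\mathrm{seq} = \frac{P_{\mathrm{actual}} -
\mathrm{med}\,P_{\mathrm{col}}}{P_{\mathrm{actual}} -
\mathrm{med}\,P_{\mathrm{row}}}$$
is near 0 for purely synchronous data and near 1 for pure sequences,
and varies monotonically with the fraction of sequential structure in
between.  Significance is assessed per dataset against the
$(1-\alpha)$ quantile of the column-shuffled powers (the Bonferroni
family is the set of shuffles for one dataset; the alternative —
correcting across experimental conditions — is the caller's
composition).  15 shuffles of each kind are the default; medians keep
the estimate robust at that count.

## The synthetic test bed

`make_sequences()` emulates the benchmark data the method was
characterized on: each sequence is 10 consecutively active neurons
separated by 3 timebins, every event convolved with a causal
exponential kernel ($\tau = 10$ bins, truncated at $5\tau$) to
resemble calcium fluorescence.  Instances are placed at uniformly
random candidate onsets with rejection of overlaps against instances
of the same sequence (overlap is judged on the 28-bin active duration;
kernel tails may overlap, and different sequences co-occur freely).
The per-sequence instance count is Poisson with mean
`target_instances_per_seq` (default 60, independent of $T$), so at the
reference scale ($T = 15000$) the across-seed spread is
$\approx\sqrt{60}\approx 7.7$, slightly wider than the $\pm 6$ the
reference condition reports — the mean matches, the dispersion is an
assumption.  Reducing $T$ at a fixed instance count makes the data
denser, not sparser.

Four noise operators act on the event log and regenerate $X$:
participation (each neuron-instance event kept with probability $p$),
additive (spurious events per cell at a given probability), jitter
(event times displaced by a rounded Gaussian, clipped to the
recording), and warping (per-instance uniform stretch factors on
$[1, 1+\mathrm{max}\%/100]$ applied to within-instance offsets, with
re-placement by rejection when stretched instances would overlap).
`make_mixture()` generates the sequenciness calibration data: 10
neurons, 3000 bins, pattern occurrences that are sequential with
probability `p_sequence` and synchronous otherwise.  Its events are
single-bin impulses by default: any kernel wider than the one-bin gap
would smear consecutive sequence events into partly synchronous
columns and dilute the synchronous/sequential contrast the score is
calibrated on.

What a green test on these fixtures does *not* establish: robustness
to non-Poisson instance statistics, amplitude heterogeneity across
neurons, bursting or refractory dynamics, slow drifts, or correlated
(shared) background — real recordings have all of these, and the
preprocessing helpers (`gaussian_smooth()`, `normalize_traces()`)
address only amplitude conditioning.

## Known limitations

- With strong penalties and a single dominant motif, near-symmetric
  states (many factors sharing one sequence at equal amplitude) decay
  only slowly; fixed iteration budgets of a few hundred iterations,
  not cost tolerances, are the reliable regime (see Stopping above).
  Occasional runs still land on a redundant local optimum at
  $\lambda \gtrsim 3\lambda_0$; the sweep-then-fit workflow and
  majority statistics over seeds are the intended use.
- Centering trades a small, bounded cost increase for interpretable,
  centered exemplars; disable with `shift_center = FALSE` if exact
  monotonicity matters more.
- The masked (cross-validation) fit holds out entries, not time
  blocks; temporal leakage between neighboring bins of the same
  neuron is mitigated by the kernel width but not eliminated.
- KL/beta-divergence losses, streaming fits, and robust objectives
  are out of scope.
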