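---
title: "Models and inference for tunable plasmid copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and inference for tunable plasmid copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnassay)
```

## The system

ColE1-family origins set their copy number through inhibitor dilution. A
priming RNA (RNA-p) transcribed toward the origin initiates replication; an
antisense inhibitory RNA (RNA-i) binds nascent RNA-p and aborts priming.
Because RNA-i is made from the plasmid itself, its concentration tracks the
copy number, closing a negative feedback loop: more plasmids mean more
inhibitor, less priming, and less replication, until replication exactly
balances dilution by host growth. `pcnassay` implements the deterministic
steady state of this loop, the inference machinery for a pooled
sequencing-based assay that measures growth rate and copy number for
hundreds of origin variants at once, the linear growth-burden model those
measurements support, single-construct phenotype estimators (plate-reader
growth and expression, droplet PCR), and an equilibrium occupancy model for
a CRISPRi effector titrated by plasmid-borne decoy sites.

## The replication model

For a variant with RNA-p initiation rate $k_p$, RNA-i initiation rate
$k_i$, RNA decay rate $\epsilon$, priming probability $\rho$, host growth
rate $r$ (all rates per minute) and $n$ rate-limiting inhibition steps, the
steady-state copy number is

$$
N_p \;=\; \frac{n\,(\epsilon + r)}{k_i - k_p}
  \left[\left(\frac{\rho\,k_p}{r}\right)^{1/n} - 1\right],
$$

with the $n \to \infty$ (exponential-inhibition) limit
$N_p = \frac{\epsilon + r}{k_i - k_p}\,\ln\!\frac{\rho k_p}{r}$. The
$n = 1$ and $n = \infty$ forms bracket hyperbolic and exponential
inhibition kinetics. Two domain boundaries have biological meaning and are
reported as regime labels rather than errors: when $k_p \ge k_i$ inhibition
cannot balance priming and replication runs away (`runaway`); when
$\rho k_p / r < 1$ replication cannot keep up with dilution and the
steady state collapses below one copy per cell (`loss_prone`).

```{r}
p <- rep_params(epsilon = 0.545, rho = 0.65, r = 0.01, k_i = 0.95,
                k_p = 0.3135, n_steps = 1)
copy_number(p)
classify_regime(p)
```

Three numerical decisions worth recording:

* **Units.** Parameter sets of this model are sometimes quoted with the
  bare unit "min"; the expression is dimensionally consistent only if
  $\epsilon, r, k_i, k_p$ are rates, so all are treated as min$^{-1}$.
* **Infinite $n$ is a sentinel**, not a large integer, so
  $(\cdot)^{1/n}$ never overflows; the suite checks that $n = 10^6$
  agrees with the closed logarithmic form to $10^{-4}$ relative error
  across random draws.
* **Burden coupling.** Copy number lowers growth (see below) and lower
  growth raises copy number. `solve_self_consistent()` iterates the two
  maps with damping 0.5, relative tolerance $10^{-8}$, at most $10^4$
  iterations, and a growth-rate floor of $10^{-6}$ min$^{-1}$ that keeps
  the model finite during iteration. A trajectory that settles onto the
  floor is not a fixed point but the signature of unbounded burden
  feedback, and is flagged `runaway_feedback` instead of being returned as
  converged.

## The pooled assay and its inference

The assay transforms a mutagenized origin library (degenerate $-35$, $-10$
and $+1$ positions of the priming-RNA promoter; $2^4 \times 2^4 \times 4 =
1024$ sequences), grows the pool to a target density, then repeatedly
dilutes 1:4 and regrows, sampling plasmid preps at each passage for
sequencing. Under the assay's assumptions — one plasmid per transformed
cell, no plasmid transfer, exponential growth throughout — two signals
separate cleanly:

* **Growth** moves read fractions *between* timepoints:
  $f_n = f_{n-1} 2^{\delta t\,(1/\tau - 1/\tau_{av})}$ for a variant with
  doubling time $\tau$ against the bulk doubling time $\tau_{av}$, so each
  adjacent pair of timepoints yields
  $1/\tau = \log_2(f_n/f_{n-1})/\delta t + 1/\tau_{av}$. The reported
  $\tau$ inverts the mean of the per-pair rates (with $k$ timepoints the
  mean telescopes to a $\log_2(f_k/f_1)$ contrast).
* **Copy number** offsets the sampled fractions relative to the ligation
  (initial library) fraction $f_i$, because sequencing libraries are made
  from plasmid preps: a variant's read share is its cell share *times* its
  copy number, while the ligation share carries no such weighting. Backing
  the accumulated growth drift out of the first sampled timepoint leaves
  the relative copy number
  $C = (f_1/f_i)\, 2^{-t\,(1/\tau - 1/\tau_{av})}$, which the package also
  evaluates at the later timepoints to feed the uncertainty estimate.

### What $\tau_{av}$ must refer to

The read fractions are normalized by the *sequenced pool* — total plasmid
mass — whereas an optical-density measurement of the bulk tracks *cell*
mass. When copy number anticorrelates with growth rate (which is exactly
the regime the burden relation creates), the two pools grow at measurably
different rates, and using the cell-pool doubling time as $\tau_{av}$
shifts every inferred division rate by a common offset and every copy
number by a time-dependent factor. The estimator is self-consistent only
when $\tau_{av}$ is the doubling time of the plasmid pool. The synthetic
generator therefore emits both: the cell-pool values for reference and the
plasmid-pool values (`tau_bulk_reads`, per interval) that the inference
consumes. With them, noise-free expected-count tables return every
variant's $\tau$ and $C$ to better than $10^{-6}$ relative error — the
suite's oracle-equivalence check. A scalar $\tau_{av}$ is accepted too,
matching how the assay would be run with a single externally measured
bulk doubling time; there is deliberately no default, since a silently
assumed $\tau_{av}$ would bias every estimate.

### Uncertainty model

Counting noise is multinomial; its first-order propagation through the
copy-number expression leaves
$\mathrm{Var}(\ln \hat C) \approx (1+u)^2/n_1 + u^2/n_k + 1/n_i$ with
$u = t/((k-1)\,\delta t)$ and $n_\bullet$ the relevant read counts. This
is combined with the across-timepoint spread of the per-timepoint $C$
values, and the total is binned into the three reporting classes
$[0, 5\%)$, $[5\%, 25\%]$, $(25\%, \infty)$. A Jeffreys-style pseudo-count
of 0.5 guards against zeros (checked to become irrelevant in the
large-count limit), and variants with fewer than 20 sampled reads are
reported unestimated rather than noisily.

### Absolute calibration

Sequencing fixes copy number only up to a common scale. Droplet-PCR
measurements of anchor constructs pin it down; a single multiplicative
factor is fit in log space with slope fixed to one. Two practical rules in
the packaged pipeline came out of validating it end to end:

* anchors are taken from log-spaced bins across the *central* (5–95%)
  quantile range of the estimates — an anchor conditioned on the smallest
  or largest estimate is conditioned on estimation error (an extreme order
  statistic) and biases the fitted scale upward by several percent;
* replicate droplet wells are pooled before the Poisson transform, and the
  reference channel is diluted so the target channel sits near
  $\lambda \approx 3$, keeping both channels well populated.

## The linear burden model

Growth rate declines linearly with copy number,
$\mu(x) = b\,(1 - a\,x)$, with $b$ the plasmid-free growth rate and $a$
the fractional burden per plasmid copy. The relation is sometimes written
as a cost magnitude $a\,b\,x$ on top of baseline $b$; since measured
growth *decreases* with copy number, the package implements the decreasing
form and treats $a$ as a positive burden fraction. For a small high-copy
vector, $a$ is comparable to the plasmid/genome length ratio
(`plasmid_genome_fraction()` returns 0.0579% for a 2686 bp plasmid against
the 4,641,652 bp E. coli K-12 chromosome), consistent with burden
proportional to the DNA-synthesis share each copy represents.

`fit_burden()` is weighted least squares of growth rate on copy number
with weights $1/\max(\mathrm{se}, 0.01)^2$ — the floor stops a single
ultra-precise point from dominating — followed by the delta method for the
variances of $(a, b) = (-\beta_1/\beta_0, \beta_0)$. Runaway- or
loss-flagged points are down-weighted (factor 0.1), not excluded,
mirroring how such points are de-emphasized rather than dropped when the
relation is displayed.

## The synthetic generator: what it emulates, and what it does not

`generate_library()` + `simulate_passaging()` + `simulate_reads()`
reproduce the statistical structure the inference assumes:

* variant strengths sampled either mechanistically on $k_p$ (copy number
  and growth then follow from the replication model coupled to the burden
  model, with runaway/loss variants excluded and counted) or directly on
  copy number (log-uniform over 1–800 by default, matching the dynamic
  range the assay is meant to cover);
* ligation fractions from a symmetric Dirichlet (concentration 5),
  mimicking uneven library representation — dispersed, but with no
  variant absent;
* deterministic exponential competition between variants, renormalized at
  each sampling (all cultures are sampled at the same optical density);
* plasmid-prep read shares proportional to cell share × copy number —
  the generator's central assumption, and the only read-share model
  consistent with the copy-number estimator above;
* multinomial sequencing at fixed depth per timepoint (default $10^6$);
* logistic plate-reader curves whose fluorescence accumulates at a rate
  proportional to copy number × OD, making the $P = G\mu/k$ estimator
  exactly invertible at zero noise;
* Poisson droplet partitioning for ddPCR.

The passaging times are not part of any published protocol, so they are
explicit parameters with defaults chosen once on first principles:
`delta_t = 90` min ($\approx \log_2 4$ bulk doublings per 1:4 passage at a
typical ~45 min bulk doubling time) and `t_first = 120` min (outgrowth of
a dense, high-efficiency transformation to sampling density). The error in
$C$ grows as $2^{t\,\delta(1/\tau)}$, so an early first sampling is the
scientifically sound design; at these settings and depth $10^6$ the median
relative copy-number error across an 830-variant library measures 5–8%,
dominated by the read-count skew that competition plus copy-number
weighting produce, and halves when depth is quadrupled (the suite asserts
the concentration-with-depth behaviour, with the median under 5% at depth
$4\times 10^6$).

Deliberately not modeled: transformation bottlenecks, plasmid transfer,
lag-time differences, per-cell copy-number noise and partitioning noise at
division (loss and runaway appear only as deterministic regime labels),
and any sequence-to-rate map — the degenerate promoter positions are
realized only so that read matching can be exercised; sequence has no
effect on simulated rates. Passing tests therefore show that the inference
is correct *under the assay's own assumptions*, not that those assumptions
hold in any particular experiment.

## Plate reader and droplet PCR

Growth rates from plate-reader curves are discrete differences of log OD
(the log form is what gives $\mu$ per-minute units compatible with
$P = G\mu/k$; a raw OD difference would not be a specific rate), averaged
over ±6 min around the maximum, with readings below OD 0.01 after blank
subtraction excluded and the blank taken as the minimum of the first five
readings — all configurable. Expression $G$ is windowed fluorescence over
windowed OD at that same point, and `fit_k()` turns anchor triples
$(G, \mu, P_{\mathrm{ddPCR}})$ into the calibration constant by
least squares through the origin.

Droplet PCR uses the Poisson relation $\lambda = -\ln(1 - p)$ per channel
and reports the target/reference ratio as plasmids per genome. The 95% CI
propagates binomial counting error through the log transform by the delta
method on the log-ratio scale — a deliberate choice over droplet-level
bootstrap, matching how such error bars are conventionally derived.
Saturated channels (every droplet positive) and empty reference channels
are flagged, not estimated. The suite checks ~95% empirical coverage over
500 seeded simulations at 20,000 droplets.

## Sponge-site occupancy

A dCas12a–crRNA effector pool of size $R$ distributes over $N_a$ active
sites, $N_c$ decoy sites (same motif, same binding energy
$\Delta\varepsilon$ in $k_BT$, relative to nonspecific binding) and
$N_{NS}$ nonspecific genomic sites. Two solution routes:

* **exact**: canonical partition-function enumeration over the number of
  specifically bound effectors, used automatically whenever
  $R\,(N_a + N_c) \le 10^6$ with integer counts;
* **mean-field**: bisection (tolerance $10^{-10}$) on the free-effector
  count in the self-consistency relation
  $p = w/(1+w)$, $w = (R_{\mathrm{free}}/N_{NS})\,e^{-\Delta\varepsilon}$,
  $R_{\mathrm{free}} = R - p\,(N_a + N_c)$.

At genome-scale $N_{NS}$ and effector counts in the hundreds the two
agree to better than $10^{-3}$; at very small molecule numbers (a handful
of effectors and sites) the mean-field answer can deviate by a few percent
because it ignores molecular-number fluctuations — e.g. occupancy 0.510
exact vs 0.469 mean-field at $R = 2$, $N_a = 1$, $N_c = 2$, $N_{NS} =
100$, $\Delta\varepsilon = -5$. The automatic switch keeps returned values
exact in that regime, and the suite pins both the agreement domain and the
exact route against a literal enumeration over occupied-site sets.

$R$ and $N_{NS}$ are rarely known; the defaults ($R = 100$,
$N_{NS} = 4.6\times 10^6$) are documented working values, not
measurements. Expression is mapped linearly to $1 - p$; fold-change is
OFF-state over ON-state expression and dynamic range their difference.
Curves against sponge-site count are evaluated at two energies
($-13.25$ and $-12.25\,k_BT$ by default) forming a plausibility envelope.

## Validation experiment

`run_burden_recovery()` is the package's end-to-end check: 830 variants
spanning copy numbers 1–800, growth rates from the burden model with
$a = 0.065\%$, $b = 0.019$ min$^{-1}$, four passages, depth $10^6$,
inference, ddPCR-anchored calibration, weighted fit. The recovered
coefficients land within the quoted uncertainties of the generating values
(the acceptance script reports them for any seed), which is the package's
evidence that the estimator chain is unbiased at realistic depth and
library size. Problem sizes throughout the suite (830 variants, $10^6$
reads, 500-replicate coverage runs, 1000-draw property sweeps) were chosen
as the smallest that exercise the claims convincingly.

## Known limitations

* The inference assumes exponential growth between samplings; saturation
  or lag heterogeneity would bias $\tau$ in ways the generator does not
  emulate.
* $C$ is anchored at the first sampled timepoint; the per-timepoint spread
  is reported as uncertainty but late-timepoint drift (population mean
  copy number shifting as fast variants take over) is not modeled out.
* Whether per-pair rates should be averaged or a single slope fit across
  all timepoints is an open design choice; per-pair averaging is
  implemented, and with the telescoping mean the difference is a weighting
  of interior timepoints only.
* The occupancy model is equilibrium-only: no binding/unbinding kinetics,
  no induction transfer function.
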