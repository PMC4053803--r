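---
title: "Model and methods behind methquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind methquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(methquant)
library(dplyr)
```

## The problem

Affinity capture of methylated DNA (MBD-seq, MeDIP-seq) is a cost-effective
way to profile DNA methylation genome-wide, but the read density over a
genomic bin confounds three things: the regional methylation level, the
CpG-density-dependent efficiency with which the assay can capture the bin at
all, and library-scale factors (sequencing depth, composition, copy number).
A bin with no reads may be unmethylated — or invisible to the assay. The
model implemented here separates these effects by analyzing the sample of
interest jointly with a fully methylated control: genomic DNA treated with
the SssI CpG methyltransferase, captured and sequenced under the same
protocol, whose read profile reveals where the assay can detect methylation.

## The observation model

For bin $i$ with sample count $y_{iS}$ and control count $y_{iC}$,

$$
y_{iS} \mid \mu_i, \lambda_i \sim \text{Poisson}\!\left(f\,
\frac{cn_i}{ccn}\, \mu_i \lambda_i\right), \qquad
y_{iC} \mid \lambda_i \sim \text{Poisson}(\lambda_i),
$$

where $\lambda_i > 0$ is the region-specific read density at full
methylation, $\mu_i \in (0,1)$ the regional methylation level, $f$ the
normalization offset between the two libraries, and $cn_i/ccn$ a
multiplicative copy-number adjustment relative to the cell's most prominent
state. The read density prior is $\lambda_i \sim \text{Ga}(\alpha_k,
\beta_k)$ with class-specific hyperparameters (below); the methylation prior
is uniform by default, or a mixture of Beta components, or a
Dirac–Beta–Dirac (DBD) mixture with point masses at 0 and 1.

Integrating $\lambda_i$ out gives the marginal posterior of $\mu_i$ in
closed form. For a Beta$(a,b)$ prior component, with $E = f\,cn_i/ccn$,
$c = \alpha + y_S + y_C$ and $z = E/(\beta + 1 + E)$,

$$
p(y_S, y_C) \propto B(y_S + a,\, b)\; {}_2F_1(c,\, b;\; y_S + a + b;\; z),
$$

and all posterior moments are ratios of such terms:

$$
\mathbb{E}[\mu^m \mid y] =
\frac{B(y_S + a + m, b)\; {}_2F_1(c, b; y_S + a + m + b; z)}
     {B(y_S + a, b)\; {}_2F_1(c, b; y_S + a + b; z)}.
$$

These expressions were derived from the Euler integral representation of the
Gauss hypergeometric function, and every formula is gated in the test suite
by an independent adaptive-quadrature oracle that integrates the raw
Poisson × Poisson × gamma × prior model directly: agreement to $10^{-6}$ on
means, variances and normalization over hundreds of random parameter draws
is a hard requirement of the suite, not an afterthought.

Without a control (the SssI-free variant, `y_c = NULL`), only the first
Poisson model is kept. The same structure applies with
${}_2F_1(\alpha + y_S,\, y_S + a;\, y_S + a + b;\, -E/\beta)$; the
parameters are identifiable only through the priors, which has practical
consequences discussed under *Limitations*.

### Atoms

The DBD point masses propagate exactly: the $\mu = 0$ atom can carry
posterior weight only when $y_S = 0$ (a Poisson with rate 0 produces no
reads), in which case its likelihood is the negative binomial mass of the
control count; the $\mu = 1$ atom's likelihood is the joint marginal
evaluated at full methylation. Posterior atom weights are returned alongside
the continuous density and participate in all intervals.

## Numerical core: the hypergeometric function

No installed R package provides ${}_2F_1$, and it is the computational heart
of the model, so `lhyp2f1()` implements it directly:

* for $0 < z < 1$ the defining series is accumulated in log scale (running
  log-sum-exp over geometrically growing chunks), so parameters in the
  thousands — $c$ grows with $y_S + y_C$ — cannot overflow; truncation stops
  when the geometric tail bound $t_n z/(1-z)$ drops below $10^{-12}$ of the
  partial sum;
* for $z < 0$ (the SssI-free branch) the Pfaff transformation
  ${}_2F_1(a,b;c;z) = (1-z)^{-a}\,{}_2F_1(a, c-b; c; z/(z-1))$ maps the
  argument into $(0,1)$ with all parameters positive. The Pfaff transform on
  the *b* parameter, sometimes recommended for $z$ near 1, is deliberately
  not used: in this model family it produces a negative upper parameter
  ($c - a = a + b - \alpha - y_C$) and an alternating series. The direct
  series converges geometrically at rate $z$ for every $z < 1$, which is
  acceptable even at $z \approx 0.999$;
* if the series has not converged within two million terms, a log-scaled
  adaptive quadrature of the Euler integral takes over.

The implementation is pinned against values computed with an
arbitrary-precision series implementation (40 significant digits) and
against closed-form identities such as
${}_2F_1(1,1;2;z) = -\log(1-z)/z$.

## Empirical Bayes by CpG-density class

Capture efficiency rises steeply with local CpG density, so one prior for
$\lambda$ genome-wide would be badly misspecified. Bins are annotated with a
weighted CpG count — CpGs within a 700 bp window around the bin center,
weighted linearly as $w(d) = \max(0, 1 - d/350)$ with $d$ the distance from
the center to the C (the window reflects typical capture fragments of
~300 bp; CpG is its own reverse complement, so scanning the forward strand
counts both) — and partitioned into $K$ density classes (default 100,
equal-count breakpoints, left-closed). Per class, $(\alpha_k, \beta_k)$, and
any free Beta shape parameters of the methylation prior, maximize the sum of
analytic log marginal likelihoods over the class's bins: Nelder–Mead on log
parameters (objective tolerance $10^{-8}$), three random restarts around a
method-of-moments initializer computed from the control counts, repeated
count tuples collapsed with multiplicities. Restart perturbations come from
a private RNG stream, so fitting is deterministic and leaves the caller's
RNG untouched.

Three robustness rules: bins whose counts exceed the class's 0.999 quantile
(interpolated; configurable) are masked from the fit but still estimated —
unusual high counts are often unannotated amplifications; classes with fewer
than 50 usable bins are merged into their nearest density neighbor; an
optimizer failure falls back to the neighbor class's parameters with a
`converged = FALSE` flag. In SssI-free mode the DBD weights stay fixed at
(0.1, 0.8, 0.1) and the Beta shapes are shared across classes by default
(block-coordinate ascent), since each class alone carries little information
about the methylation prior; per-class shapes are available via
`ab_shared = FALSE`.

Integrating $\lambda$ out of the control model alone yields a negative
binomial prior predictive per class (size $\alpha_k$, success probability
$\beta_k/(\beta_k+1)$), exposed by `prior_predictive_sssi()` and
`autoplot()` on the fit as a mean-and-band display against CpG class — the
standard visual check that the fitted priors track the observed
depth–density relation.

## Normalization and copy number

The offset $f$ converts the control's read-rate scale to the sample's. On an
MA representation of a random subsample of bins (default 50,000; both counts
positive), $\hat f = 2^{\text{median}(M \,\mid\, A \ge q_A)}$ with $q_A$ the
0.998 nearest-rank quantile of $A$: the highest-$A$ bins are essentially
fully methylated, so their median log-ratio isolates depth and composition.
Zero-count bins are excluded rather than pseudocounted — only high-$A$ bins
enter the median, where zeros cannot occur. With copy-number variation, only
bins at the most prominent state `ccn` are used. In SssI-free mode $f$ is
fixed *before* the fit at the 0.99 nearest-rank quantile of the sample
counts (restricted to `ccn` bins when states are known); its interpretation
shifts to the count level of bins "at risk" of full methylation.

Copy-number states enter as the exact multiplier $E_i = f\,cn_i/ccn$; bins
whose segment is unknown take `ccn` (neutral multiplier) with a flag, and
state 0 yields $E_i = 0$ with a no-capture flag.

A caveat established while validating at desk scale: the MA median is
consistent only when the selected bins are truly fully methylated, which in
practice requires read densities of hundreds per bin (CpG islands at genome
scale). In simulations capped at $\lambda \lesssim 40$ the estimator is
biased low by ~10%; the package's own calibration checks therefore separate
offset recovery (run at high depth) from copy-number behavior (run at a
fixed offset).

## Credible intervals

Three types, from the same closed-form posterior:

* **HPD** — the shortest interval holding the requested mass, found by
  minimizing $Q(t + \gamma) - Q(t)$ over $t$, where $Q$ is the posterior
  quantile function built from a gridded CDF (2048 cells by default, half
  uniform and half spaced at equal posterior mass from a coarse first pass,
  with geometric refinement toward 0 and 1 for priors whose density diverges
  there). Atoms are absorbed at their exact locations; when the equivalent
  density superlevel set is disjoint the smallest covering interval is
  returned with a `multimodal` flag.
* **Quantile** — equal-tailed, by monotone inversion of the same CDF; an
  atom can pin a bound to exactly 0 or 1.
* **Wald** — delta-method on the logit scale:
  $\mathrm{logit}(\hat\mu) \pm z_\gamma \hat\sigma$ with $\hat\sigma =
  \sqrt{\operatorname{Var}(\mu)}/(\hat\mu(1-\hat\mu))$, back-transformed, so
  bounds stay inside $(0,1)$. $z_\gamma$ comes from `qnorm`, which
  reproduces 1.96 at the 95% level.

The test suite checks HPD against a brute-force shortest-window search,
quantile bounds against sampling-importance-resampling from the raw model,
and — the property that matters — that on data simulated from the model the
95% intervals cover the true $\mu$ at a near-nominal rate.

## The simulator

`simulate_methylation_dataset()` draws from exactly the generative model
above: class label, $\lambda$ from the class gamma, $\mu$ from the prior,
copy-number states in contiguous segments (default runs of 50 bins, since
real segmentations are long-range), then Poisson counts. Default class
priors make the control depth rise from about 2 to 40 reads per 100 bp bin
across classes with moderate overdispersion, emulating the empirical
depth–density relation of MBD capture at typical sequencing depth; the
default ships with $K = 10$ classes to keep test runs fast, and synthetic
CpG densities are assigned monotonically in class so the annotation stage
can be exercised end to end. RNG streams are split per component (density,
methylation, copy number, counts): toggling one leaves the others
bit-identical. `simulate_reads()` inverts the fragment-midpoint counting
rule so that re-counting emitted reads reproduces the count table exactly.

What the simulator deliberately does not model: sequencing error, PCR
duplicates, fragment-length variability, mappability structure, and spatial
correlation of methylation along the genome. Passing calibration on
simulated data therefore demonstrates internal consistency of model,
estimator and intervals — not robustness to the ways real capture data
depart from a Poisson–gamma world (batch effects, duplicated reads,
misannotated copy number).

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to make every stochastic
tolerance comfortable without heroic runtimes: 5,000 bins per class for
hyperparameter recovery (relative error of $\hat\alpha$ well under 10%),
10,000 bins for interval calibration (Monte Carlo standard error ~0.2% on a
95% coverage), 12,000 bins over four copy-number states for the offset
comparison, 50,000 bins for offset recovery. Series tolerance is $10^{-12}$,
quadrature tolerances $10^{-9}$ to $10^{-11}$, the posterior variance is
clipped at zero only for magnitudes below $10^{-12}$ (floating-point guard,
warned), and interval grids use 2048 cells.

Coordinates are 0-based half-open throughout; trailing partial bins are
dropped when tiling (a 158,821,424 bp chromosome at 100 bp yields exactly
1,588,214 bins). Reads are assigned to the single bin containing their
extended-fragment midpoint — at 100 bp resolution an overlap rule would
multi-count every fragment. Ties in Spearman correlations use average ranks;
depth stratification presets follow the capture-depth quintile scheme, and
the CpG-island preset threshold is a density of 12.46 under the 700 bp
linear window.

## Design choices that were genuinely open

* The linear CpG weighting kernel is stated explicitly
  ($w(d) = \max(0, 1 - d/(W/2))$) because upstream descriptions of density
  calculators leave the kernel implicit; `weighting = "uniform"` is provided
  for sensitivity analysis and equals a plain CpG count.
* Equal-count (quantile) class breakpoints were chosen over equal-width
  ones: they keep per-class fits equally powered across the heavily skewed
  density distribution. Ties merge breakpoints and reduce $K$ with a
  warning.
* The masking quantile uses the interpolated (type 7) estimator rather than
  nearest-rank so that a single extreme outlier is masked even in small
  classes, while constant counts never are.
* `quantify_methylation()` never drops a bin: mappability-filtered bins are
  returned with `NA` estimates and a status, masked bins are estimated but
  labeled, and zero-control bins are estimated with appropriately wide
  posteriors and a `no_capture` flag — distinguishing "can't see" from
  "unmethylated" is the model's point.

## Known limitations

* **SssI-free identifiability.** The SssI-free marginal likelihood has a
  near-flat ridge: materially different $(\alpha, \beta, a, b)$ produce
  nearly identical count distributions at realistic sample sizes, so fitted
  hyperparameters should be read as a predictive description, not as
  estimates of interpretable quantities. The test suite checks the fitted
  model's distributional closeness to truth rather than raw parameter
  recovery for this mode. With a control, recovery is sharp.
* A flat methylation prior shrinks estimates away from the boundaries: at
  full methylation and moderate depth, posterior means plateau around
  0.85–0.95. This is the bias–variance price of the prior, visible in the
  package's own calibration runs.
* The HPD of a genuinely multimodal posterior (e.g. strong atoms at both
  ends with a thin middle) is a union of intervals; the single covering
  interval returned here over-covers, and the `multimodal` flag should be
  consulted.
* Neighboring bins are treated independently; spatial smoothing is out of
  scope.

## Session info

```{r}
sessionInfo()
```
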