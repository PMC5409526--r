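---
title: "Exon CNV calling from panel read depth: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon CNV calling from panel read depth: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcnv)
```

## The inference problem

Exon-targeted panels sequence a few dozen exons very deeply in pooled
batches. CNV breakpoints almost never fall inside the targeted exons, so a
whole-exon deletion or duplication is visible only as that sample's read
depth at the affected exons dropping to ~50% or rising to ~150% of its
expected value. The expected value is not knowable from the sample alone —
per-exon depth varies over more than an order of magnitude with probe
efficiency — but probe effects are *shared across the batch*, so the rest of
the batch can serve as the control.

`panelcnv` formalises this in three layers: reference selection, a
beta-binomial read-share model, and a distance-aware HMM.

## Reference selection

For test sample $t$, every other sample is ranked by the Pearson correlation
of raw per-exon counts with $t$ (exons with zero count in all samples are
excluded; a zero-variance vector yields correlation 0 with a warning).
Correlation is computed on raw counts because that is the scale on which the
conventional 0.98 QC threshold is defined.

Rather than fixing the number of reference samples, each prefix of the
ranking ($k = 1,\dots,$ `max_refs`, default 10) is evaluated: the prefix's
counts are summed into an aggregate reference, the model below is fitted,
and the prefix maximising the *expected log-likelihood ratio in favour of a
heterozygous single-exon deletion* is chosen (ties go to the smaller
prefix). This criterion directly optimises what the caller is for: power for
the weakest clinically important signal. Adding a well-correlated sample
grows the totals $n_i$ and sharpens the proportion; adding a poorly
correlated one inflates the overdispersion and is rejected by the criterion.

The expectation is evaluated deterministically by 16-point normal-quantile
quadrature over the moment-matched CN1 beta-binomial (exhaustive summation
over counts would cost $O(\sum_i n_i)$ per prefix for no measurable accuracy
gain at panel depths).

## The beta-binomial read-share model

Let $x_i$ be the test count at exon $i$ and $n_i = x_i + r_i$ the test plus
aggregated-reference total. Under normal copy number,

$$x_i \mid n_i \sim \mathrm{BetaBin}(n_i, \mu, \phi), \qquad
\alpha = \mu\frac{1-\phi}{\phi},\;\; \beta = (1-\mu)\frac{1-\phi}{\phi},$$

with mean share $\mu$ (roughly $1/(k+1)$ for $k$ references) and intraclass
correlation $\phi \in [0, 0.5]$; $\phi = 0$ is the binomial limit, and the
variance is $n\mu(1-\mu)(1 + (n-1)\phi)$. Because both test and reference
see the same probe efficiencies, those cancel in the proportion and a single
global $(\mu, \phi)$ suffices.

$(\mu,\phi)$ is fitted by maximum likelihood (`optim`, L-BFGS-B, $\mu$
initialised at $\sum x / \sum n$); on optimiser failure the fit falls back
to the initial $\mu$ with $\phi = 10^{-4}$ and a `converged = FALSE` flag.
Numerically, the binomial branch is taken for $\phi < 10^{-8}$: below that,
the beta-binomial correction to the log-likelihood is $O(n^2\phi)$ while
`lbeta()` with $\alpha, \beta \sim 1/\phi$ loses more precision to
cancellation than the correction is worth.

**Outlier trimming.** Inside the calling pipeline the fit is repeated after
dropping the ~6% of exons with the largest absolute standardised residual
under the initial fit (`trim = 0.06`; `fit_betabin()`'s own default is the
plain ML fit, `trim = 0`). On a 49-exon panel a single *real* CNV exon
otherwise inflates the global $\phi$, deflates the selection criterion, and
can collapse the reference set to one sample — blunting detection of the
very signal being sought. Trimming makes $\phi$ an estimate of the
normal-copy noise.

## Copy-number states and the HMM

A copy-number state $c \in \{1, 2, 3\}$ rescales the expected share on the
odds scale:

$$\mu_c = \frac{c\,\mu}{c\,\mu + 2(1-\mu)},$$

so $\mu_2 = \mu$, and a heterozygous deletion halves the test sample's
contribution. The emission matrix holds
$\log \mathrm{BetaBin}(x_i \mid n_i, \mu_c, \phi)$ per exon and state.

States evolve along the exon order with distance-dependent transitions.
With gap $d$ between adjacent exons, $e = e^{-d/L}$, and CNV-entry prior
$q$:

- normal row: $(q,\; 1-2q,\; q)$ for every $d$;
- CNV row: stay $= e + (1-e)q$, to normal $= (1-e)(1-2q)$, to the other CNV
  state $= (1-e)q$.

At $d = 0$ a CNV always persists; at $d = \infty$ (chromosome changes) every
row collapses to the prior, so adjacent exons become independent and calls
never span chromosomes. The initial distribution equals the prior row, so
the first exon of a chromosome can be called with the same prior as any
other — first-exon events are not blind spots. Defaults: $q = 0.01$,
$L = 5\times 10^4$ bp, both exposed on the CLI (`--transition-prob`,
`--cnv-length`) since $q$ trades sensitivity against false discovery.

Decoding is exact Viterbi in log space; ties break to normal, then
deletion (conservative for clinical review). Maximal runs of `del`/`dup`
become calls, each reporting a log10 Bayes factor
$\sum_i [\log_{10} P(x_i \mid c) - \log_{10} P(x_i \mid 2)]$ over the span,
observed and expected read counts ($\sum \mathrm{round}(n_i\mu)$), their
ratio, spanned genes and custom exon numbers, and the sample's QC context.
Coordinates are reported 1-based inclusive (inputs are 0-based half-open
BED).

## QC

Two flags, both annotating and never suppressing calls: samples whose best
correlation with any other sample is below `min_correlation` (default 0.98),
and exons whose median count across samples is below `min_coverage` (default
100; the even-size median is the mean of the central pair, and equality
passes). A genuine multi-exon CNV itself depresses its carrier's
correlation — a flagged sample with a call is information, not an error.

## The simulation studies

**Spike-ins.** `single_exon_sensitivity()` repeats, per exon and kind:
pick a random sample from a CNV-negative pool, scale that single cell by
0.5 or 1.5 (rounding half away from zero), re-run the full caller, and
score a success when a call of the spiked kind overlaps the spiked exon.
Each (exon, kind) pair uses its own derived RNG substream, so results for
one exon are independent of which others are evaluated.

**Read resampling.** To emulate depth $f\times$ native, every count is
replaced by one $\mathrm{Binomial}(n \cdot \mathrm{count}, p)$ draw with
$np = f$ — equal in distribution to replicating each read
$N_r \sim \mathrm{Binomial}(n, p)$ times. For $f \le 1$, $(n, p) = (1, f)$
is exact Poisson thinning; for $f > 1$, $n = \lceil 10f \rceil$,
$p = f/n$ keeps the variance within ~10% of the mean (the closest binomial
approximation to Poisson replication). `grid_experiment()` draws replicate
pools without replacement, resamples, calls every member, and scores
against the implant truth, excluding no-CNV replicates from sensitivity and
all-CNV replicates from specificity before averaging.

## The synthetic generator

`simulate_pool()` draws counts negative-binomially with mean
$m \cdot e_i \cdot s_j \cdot c_{ij}/2$: shared log-normal probe
efficiencies $e_i$ (log-sd 0.5), per-sample library factors $s_j$ (log-sd
0.1), NB size 1000 (~3% extra-Poisson noise), $m = 1000$ reads/exon, 48
samples by default. The defaults are calibrated so the generator produces
the regime the caller (and its QC defaults) assume: with between-exon
variance $V = e^{\sigma_e^2}(e^{\sigma_e^2}-1)$ and per-cell noise
$\mathrm{CV}^2 \approx 1/m + 1/\mathrm{size}$, the expected inter-sample
correlation on raw counts is $r \approx V/(V + (1+V)\mathrm{CV}^2) \approx
0.99$ at these values — comfortably above the 0.98 QC threshold, as real
pooled-capture batches are. A noisier parameterisation (e.g. probe log-sd
0.3 with NB size 200) would put clean batches *below* their own QC
threshold, which no functioning assay does. The default panel is two
BRCA-like genes (23 exons/~80 kb forward, 26 exons/~85 kb reverse — custom
exon numbers descend with coordinate on the reverse strand) on separate
synthetic chromosomes.

Problem sizes in the shipped studies (48/96 samples, ~1000 reads/exon, 100
spike repeats, 50 grid replicates) were chosen to finish in minutes on one
CPU while leaving the conclusions unambiguous.

## Limitations

- **Majority-of-panel CNVs are unidentifiable.** The model has one global
  $\mu$; a CNV spanning $\gtrsim$ half the panel's exons shifts the fitted
  $\mu$ itself instead of standing out against it (verified empirically:
  a 26-of-49-exon duplication is absorbed, while the same gene on a
  79-exon, three-gene panel is called with exact span). This is inherent to
  any self-normalising read-share model, not a tuning issue; panels should
  be designed, or batches analysed, so no single event can dominate the
  target list.
- Integer copy-number states only; mosaics and CN0-vs-CN1 distinction are
  out of scope (homozygous deletions are still *called*, as deletions).
- No GC or mappability covariates; no sex-chromosome ploidy model.

## A minimal run

```{r example, eval = FALSE}
panel <- make_panel(seed = 7)
pool <- simulate_pool(sim_spec(
  n_samples = 48,
  implants = list(list(sample = 9, gene = "GENEA", exons = c(6, 8),
                       kind = "deletion")),
  seed = 11), panel)
fit <- cnv_call(pool$matrix, "S09")
fit
plot(fit, pool$matrix)
```
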