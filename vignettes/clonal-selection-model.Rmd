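---
title: "Modeling clonal selection through a bottleneck: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clonal selection through a bottleneck: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experiment and the question

clonedrift analyzes a paired-passage cell-culture design: a population of
primary cells is sampled down to a small founder population (200 cells
per well), expanded in vitro for 13--17 population doublings, and deep
targeted sequencing (~290 kb, mean coverage ~1656x) is performed on DNA
taken before and after the expansion. A somatic variant whose allele
frequency changes between the two passages may simply reflect genetic
drift -- the bottleneck is severe and the early growth is stochastic --
or it may mark a clone under positive selection. The package provides
the null model for drift, a significance test for each site's frequency
change, and a maximum-likelihood estimator of the selection coefficient
for sites inconsistent with drift.

## The stochastic model

The model is a two-stage Markov chain on allele frequency.

**Bottleneck.** Given a true pre-expansion mutant-lineage frequency
$f_0$, the number of mutant founder cells is $J \sim \mathrm{Binomial}(B,
f_0)$ with $B = 200$.

**Growth.** The population then grows from $B$ to $N = B \cdot 2^d$
cells (default $d = 15$) by single division events: at each event one
cell is chosen to divide, with weight $1$ for wild-type cells and $1+s$
for mutant cells. This fitness-biased urn is the jump chain of two
independent Yule processes with split rates $1+s$ and $1$, which is how
we both simulate it exactly (`simulate_growth(method = "exact")`, in
compiled code) and approximate it analytically at experimental scale.
For a Yule process the scaled population size converges almost surely,
so the mutant and wild-type founder groups converge to
$W_m \sim \mathrm{Gamma}(J)$ and $W_w \sim \mathrm{Gamma}(B-J)$ and the
final mutant fraction $x$ at total size $N$ solves

$$W_m v^{1+s} = xN, \qquad W_w v = (1-x)N$$

for the shared time variable $v = e^t$. Eliminating $v$ gives a
one-dimensional integral for the CDF of the final frequency, evaluated
by equal-probability quadrature over $W_w$ (256 nodes). For $s = 0$ this
reduces *exactly* to the classical neutral result
$x \sim \mathrm{Beta}(J, B-J)$, whose mean $J/B$ is the drift
martingale. When $N \le 4096$ the package instead runs an exact dynamic
program over division events and works on the exact count support; the
event-level Monte Carlo simulator is the arbiter for both regimes
(total-variation agreement is part of the test suite).

The asymptotic kernel's error relative to the exact division process is
$O(1/\sqrt{N})$ in the final frequency; at the default
$N \approx 6.6\times 10^6$ this is far below the frequency-grid
resolution, and at $N$ around $10^3$--$10^4$ the measured
total-variation distance against $5\times 10^4$ exact replicates is
below 0.01.

**Reads.** A read covering the site reports the alternate allele with
probability $q(f) = f(1-\epsilon) + (1-f)\epsilon/3$, where $\epsilon$
is the per-base miscall rate and miscalls distribute uniformly over the
three non-source bases. Allele counts are binomial in the site depth.
By default allele frequencies are modeled directly (one lineage carries
one allele copy); a diploid mode (`diploid = TRUE`, read fraction equal
to half the cell fraction) is available but off by default, because
observed late frequencies above 50% are inconsistent with a strictly
heterozygous-cell reading.

## The drift test

`drift_pvalue()` conditions on the early-passage count through a
posterior on $f_0$ (uniform prior on frequency, binomial read
likelihood; because $q$ is linear in $f$ each quadrature cell has an
exact incomplete-beta mass). The uniform prior is a deliberately
minimal assumption that handles observed zero counts without forcing
$f_0 = 0$: an unobserved variant can still have entered the bottleneck.
The founder distribution, the neutral growth kernel, and binomial read
sampling at the late depth then give the null distribution of the late
count, and the p-value is the one-sided tail in the direction of the
observed frequency change. Tails are accumulated in log space, so
p-values far below double underflow are still reported through
`log10_p`. Significance is assessed against a Bonferroni-corrected
threshold $\alpha = 0.05 / 2.9\times 10^5 \approx 1.7\times 10^{-7}$,
dividing by the target-region size in base pairs rather than by the
number of discovered variants.

## Selection estimation

For sites rejecting drift, `estimate_selection()` evaluates the same
chain with the selected growth kernel over a grid $s \in [-1, 1]$ in
steps of 0.05 (published estimates and interval bounds are multiples of
0.05) and maximizes the log-likelihood of the observed late count; ties
resolve to the smallest $|s|$. The 95% confidence interval is the set of
grid values not rejected by the likelihood-ratio test at the
$\chi^2_1$ cutoff ($2\Delta\ell \le 3.84$), reported as the smallest and
largest grid values satisfying the inequality. Likelihoods are floored
at $10^{-300}$ so profiles stay finite.

Two numerical choices matter here. First, the early posterior is
evaluated on a fine quadrature (2048 cells over the posterior's
support) independent of the reporting grid, because with zero observed
alternate reads the posterior mass sits well inside the first few grid
bins. Second, growth kernels are memoized per (founder count, $s$,
geometry), which makes batch analyses and the grid search over $s$
shareable across sites.

## The variant screen

`screen_pair()` re-implements the two-step empirical discovery rule on
paired pileups downstream of mapping-quality and base-quality filtering
(both at 30): (a) call an alternate allele in a passage when its
Poisson-binomial error p-value -- each read contributing success
probability $10^{-Q/10}/3$ -- is below 0.01 after a dynamic Bonferroni
correction; (b) keep sites called in exactly one passage. Sites called
in both passages feed `shared_site_outliers()`, which flags
between-passage frequency differences exceeding the mean plus three
standard deviations over all shared sites. Candidates then pass a
50 bp neighborhood filter (adjacent-position pairs are first merged
into dinucleotide events such as CC>TT, the UV-damage signature) and a
minimum alternate count of 3, motivated by validation data in which all
error-driven calls carried at most 2 reads.

The correction in (a) multiplies the raw p-value by the number of
screened positions. This choice was examined quantitatively: correcting
only by the number of tests actually performed leaves the per-test
cutoff near $7\times 10^{-7}$ and produces on the order of 0.4 false
calls per variant-free 290 kb experiment at 1500x, while the
positions-based correction (cutoff $3.4\times 10^{-8}$) leaves about
0.02 -- a screen that is quiet on null data, at the cost of missing
variants observed with exactly 8 alternate reads in a narrow
depth window (roughly 1430--1600x, where 8 reads still amount to 0.5%
frequency). Variants with 9 or more supporting reads are called at any
depth at which they reach 0.5% frequency. The homozygous-host gate
(reference fraction at least 0.98) is applied in the passage *without*
the call, which keeps the screen symmetric under passage relabeling;
shared sites are not gated, since germline heterozygous sites are
exactly the background the outlier rule needs.

## The synthetic-data generator

`simulate_experiment()` forward-simulates the whole design under known
truth: per-site log-normal depths (sdlog 0.25, mean set to the study's
1656x; the published per-sample means span 661--2856x, and no per-site
family is published, so the log-normal is a committed package choice),
constant Q30 phred emission matching the quality floor, uniform
miscalls at rate $\epsilon$, and for each configured variant a binomial
bottleneck draw followed by a growth draw under its own $s$ (event-exact
when the final population is at most 65536 cells, the Yule sampler at
full scale). The generator reproduces read-count noise, depth
dispersion, bottleneck extinction and stochastic clone growth; it does
not emulate alignment artifacts, strand bias, PCR duplicates, indels or
position-correlated error, so passing screens on synthetic data speak
to the statistical rules, not to upstream read processing.
`simulate_doped_library()` emulates the detection-limit experiment, in
which DNA from a second individual is mixed in at fraction 0.2--0.4%
and detection is evaluated at host-homozygous sites against the
genotype-implied expectations; calling there uses the simple
minimum-count rule (3 reads) that the original mixture evaluation's
pileup-based approach implies, not the full screen.

## What the tests hold the package to

The suite pins, among other things: binomial bottleneck examples by
hand; the neutral Beta limit in mean and variance; total-variation
agreement (< 0.02) between analytic growth kernels and $5\times 10^4$
event-exact replicates; agreement of `drift_pvalue()` with an
independent $10^5$-replicate Monte Carlo of the entire null chain on
small geometries within three Monte Carlo standard errors; a neutral
calibration experiment (2000 low-frequency sites at 1500x, false-positive
rate at $\alpha = 0.05$ below nominal plus three binomial standard
errors -- the discrete test is conservative); and parameter recovery at
$s = 0.4$ (early frequency 0.5%, depth 2000x, three replicate
experiments of 200 sites). Recovery is evaluated on lineages that
survive the bottleneck: at a 0.5% early frequency roughly 37% of
variants draw zero mutant founders, the selection coefficient never
acts on them, and their estimates are driven toward $-1$ by
construction; including them would test bottleneck extinction, not
estimation. Under those conditions the median estimate falls within
one to two grid steps of the truth (a small downward pull comes from
the uniform prior's founder inflation at low counts) and the
likelihood-ratio intervals cover the truth in about 92--93% of
surviving sites -- slightly under nominal, as expected for a
single-observation likelihood-ratio interval snapped inward to the grid.

Problem sizes in the routine suite are chosen to keep the whole run in
a few minutes on one CPU: total-variation oracles run at $d = 4$--$6$
(where every division event can be simulated $5\times 10^4$ times), the
chain Monte Carlo oracle at $B \le 20$, and the screen calibration over
100 full-size variant-free experiments, which are cheap because only
counts are simulated.

## Worked example

```{r}
library(clonedrift)

params <- experiment_params()          # B = 200, d = 15, eps = 1e-3
cdkn2a <- site_observation("chr9:21974774:A", 0, 725, 156, 282)

drift_pvalue(cdkn2a, params)           # p ~ 2.3e-41, gain, significant
estimate_selection(cdkn2a, params)     # s_hat = 0.55, 95% CI [0.40, 0.85]
```

## Known limitations

* The growth realization (division-event urn / Yule limit) is one
  concrete reading of a "modified Moran model of population growth";
  published p-values from the original analysis are therefore treated
  as order-of-magnitude bounds, and selection estimates agree with the
  published values to within one grid step (0.05).
* Single bottleneck only: no serial passaging, cell death, senescence
  or asynchronous cycling.
* Sites are modeled independently; no haplotype linkage between
  variants and no joint multi-site inference.
* The screen assumes quality-filtered pileups; it does not model
  alignment artifacts and performs no indel or strand-bias handling.
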