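# clonedrift

Detecting clonal selection during in vitro cell aging from paired
early/late-passage deep-sequencing allele counts.

## The problem

In a limited-expansion cell-culture experiment, a primary cell
population is bottlenecked to ~200 founder cells, expanded for 13–17
population doublings, and deep targeted sequencing (~290 kb at ~1656×
mean depth) is performed before and after expansion. Somatic variants
whose allele frequency differs between the two passages are candidates
for positive selection — but a 200-cell bottleneck and stochastic early
growth generate large frequency changes by drift alone. clonedrift is
for researchers who need to decide, site by site, whether an observed
change exceeds what drift can explain, and if so, how strong the
selective advantage is.

## The model

Allele-frequency change is modeled as a two-stage Markov chain:

1. **Bottleneck** — the mutant founder count is
   $J \sim \mathrm{Binomial}(B, f_0)$ with $B = 200$;
2. **Growth** — the population grows to $N = B\,2^d$ cells by single
   division events in which a mutant cell divides with relative weight
   $1+s$ (a fitness-biased urn; the jump chain of two independent Yule
   processes). Neutrally ($s=0$) the final frequency is
   $\mathrm{Beta}(J,\,B-J)$, with mean $J/B$ (the drift martingale);
   with selection the final frequency solves the Yule race
   $W_m v^{1+s} = xN$, $W_w v = (1-x)N$ with
   $W_m \sim \Gamma(J)$, $W_w \sim \Gamma(B-J)$.

Reads report the alternate allele with probability
$q(f) = f(1-\epsilon) + (1-f)\,\epsilon/3$. The drift test conditions on
the early count, propagates it through bottleneck and neutral growth,
and returns the one-sided tail probability of the late count, compared
with a Bonferroni threshold $\alpha = 0.05/2.9\times10^5 =
1.7\times10^{-7}$. The selection coefficient is estimated by a grid
search over $s \in [-1,1]$ (step 0.05) maximizing the likelihood of the
late count, with a 95% CI from the likelihood-ratio test
($\chi^2_1$, $2\Delta\ell \le 3.84$).

The package also provides the upstream somatic-variant screen
(quality-aware Poisson-binomial calling on paired pileups, shared-site
outlier detection, neighborhood and dinucleotide handling), a
sensitivity/specificity evaluator for doped DNA mixtures, and a
synthetic-data generator that emulates the full experiment with known
ground truth.

## Worked example

The three published sites with significant frequency change, from their
printed allele counts:

```r
library(clonedrift)

params <- experiment_params()   # B = 200, d = 15, eps = 1e-3

cdkn2a <- site_observation("chr9:21974774:A", 0, 725, 156, 282)
drift_pvalue(cdkn2a, params)
#> Drift-null test for chr9:21974774:A: p = 2.319e-41 (log10 p = -40.63), gain
#>   SIGNIFICANT at Bonferroni alpha = 1.72e-07

estimate_selection(cdkn2a, params)
#> Selection estimate for chr9:21974774:A: s_hat = 0.55, 95% CI [0.40, 0.85]

sites <- data.frame(
  site_id     = c("chr9:21974774:A", "chr5:60169670:T", "chr13:32914714:T"),
  early_alt   = c(0, 0, 42),    early_total = c(725, 2168, 3122),
  late_alt    = c(156, 122, 642), late_total = c(282, 705, 2996))
analyze_sites(sites, params)[, c("site_id", "p_value", "s_hat", "ci_low", "ci_high")]
#>            site_id      p_value s_hat ci_low ci_high
#> 1  chr9:21974774:A 2.319106e-41  0.55   0.40    0.85
#> 2  chr5:60169670:T 5.770248e-15  0.35   0.25    0.60
#> 3 chr13:32914714:T 2.372071e-13  0.30   0.20    0.50
```

All three sites reject the drift null far beyond the corrected
threshold, and all three carry strong positive selection estimates
(ŝ ≥ 0.30), each inside the corresponding published confidence
interval. A variant rising from 0/725 to 156/282 reads (0% → 55.3%)
under pure drift would require the fortuitous expansion of a founder
lineage that the model prices at p ≈ 10⁻⁴¹.

A thin command-line interface (`exec/clonedrift`) exposes the pipeline
as subcommands (`simulate`, `screen`, `test`, `estimate`,
`mixture-eval`, `report`); see the methods vignette
(`vignettes/clonal-selection-model.Rmd`) for the model, its
assumptions, and all tunable parameters.

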