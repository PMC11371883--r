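# kinabund

Close-kin mark-recapture (CKMR) abundance estimation from a **single
sampling event**, for small, stage-structured populations of birth-pulse
species — the setting faced by managers of woodland caribou herds sampled
once, by winter fecal-DNA surveys, 6–8 months after calving.

CKMR treats each sampled offspring as a "mark" on its mother: among all
pairwise comparisons between sampled calves and sampled reproductive
females, the frequency of true mother–calf pairs is inversely related to
the number of reproductive females `N_F` alive at the cohort's birth. The
package provides:

* an **individual-based, female-only simulator** of one annual cycle
  (birth pulse with maternity tracking, six months of stage-specific
  survival, a single random survey of survivors);
* the **stage-stratified multinomial pseudolikelihood estimator** of
  `N_F`. A comparison involving a female of stage *s* is a pair with
  probability

  ```
  q_s = b_s f / ( N_F (b_s f (1 − A) + b_a f A) )
  ```

  (`b_s`, `b_a` stage breeding probabilities, `f` calves per breeder —
  which cancels — and `A` the adult share of sampled reproductive
  females), maximized over a bounded range with 95% profile-likelihood
  intervals (the 1.92 log-likelihood-unit drop);
* a **simulation-study engine** (`run_cell()`, `run_grid()`) summarizing
  accuracy, precision and interval coverage over grids of population size
  and sampling fraction;
* the **single-year binomial estimator** for annual field surveys,
  `MO_t ~ Binom(n_c,t × n_f,t, 1/N_f,t)`, with profile intervals, plus
  the Tonquin herd (Jasper National Park) 2006–2015 survey counts as a
  bundled case study.

## Worked example: the Tonquin case study

```r
library(kinabund)

est <- annual_abundance(tonquin_counts())
dplyr::select(est, year, n_comparisons, mop, pct_pairs, estimate, ci_low, ci_high)
#> # A tibble: 10 × 7
#>     year n_comparisons   mop pct_pairs estimate ci_low ci_high
#>    <dbl>         <dbl> <dbl>     <dbl>    <dbl>  <dbl>   <dbl>
#>  1  2006           256     4     1.56        64     28     205
#>  2  2007           140     1     0.714      140     32    2445
#>  3  2008           196     2     1.02        98     32     587
#>  4  2009            96     3     3.12        32     13     127
#>  5  2010           144     4     2.78        36     16     115
#>  6  2011           176     8     4.55        22     12      48
#>  7  2012            40     2     5           20      7     118
#>  8  2013            84     3     3.57        28     11     111
#>  9  2014            56     5     8.93        11      5      30
#> 10  2015            24     3    12.5          8      3      31
```

Each row is one winter: `n_comparisons = n_calves × n_mothers` pairwise
kinship comparisons, of which `mop` were mother–calf pairs; the estimate
is the binomial MLE `n_comparisons / mop` (integer-reported) with its 95%
profile interval. In 2011, 8 pairs among 176 comparisons (4.55%) give
`N_f ≈ 22` females, interval (12, 48). Years with one or two pairs (2007,
2008) are barely constrained from above — a single pair among 140
comparisons is consistent with anything up to a few thousand females.

```r
multi_year_summary(est, 2009:2015)
#> # A tibble: 1 × 2
#>   n_years mean_estimate
#>     <int>         <dbl>
#> 1       7          22.4
```

## Design evaluation by simulation

```r
cell <- run_cell(population_config(250), proportion = 0.5,
                 replicates = 200, master_seed = 10)
dplyr::glimpse(cell)
#> $ n_f           <dbl> 250
#> $ proportion    <dbl> 0.5
#> $ replicates    <dbl> 200
#> $ flat_fraction <dbl> 0
#> $ mean_mop      <dbl> 16.345
#> $ mean_n_hat    <dbl> 257.1643
#> $ sd_n_hat      <dbl> 42.47917
#> $ cv            <dbl> 0.165183
#> $ q2_5          <dbl> 187.6832
#> $ q97_5         <dbl> 358.8962
#> $ mean_bias     <dbl> 0.02865737
#> $ median_bias   <dbl> 0.01062048
#> $ coverage      <dbl> 1
```

Sampling half the survivors of a 250-female population yields ~16 pairs
per survey and an estimator with ~3% mean bias, CV 0.17 and conservative
interval coverage. `run_grid()` maps whole designs;
`plot_grid_summary()` and `plot_annual_estimates()` draw the standard
figures, and `expected_mop()` gives the closed-form expected pair count
for quick power reasoning. A thin command-line wrapper
(`inst/cli/kinabund.R`; subcommands `simulate`, `grid`, `estimate`) runs
the same workflows from a shell.

See the vignette (`vignettes/single-survey-ckmr.Rmd`) for the model, its
assumptions, and every numerical convention.

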