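# gcnorm

Gene-level normalization of RNA-Seq read counts for **sample-specific
GC-content bias**, with a negative binomial differential expression
test and an evaluation harness, for analysts working with lane-level
count tables (bulk RNA-Seq, and count matrices more generally).

Within a sequencing lane, the expected read count of a gene depends on
the GC fraction of its sequence, typically rising and then falling with
GC — and the shape of that dependence differs between library
preparations. Because the effect is not shared across samples, it does
not cancel in count ratios: fold-change estimates and differential
expression (DE) calls become biased toward GC-rich genes. `gcnorm`
removes the bias one lane at a time, then adjusts between-lane
distributional differences such as sequencing depth, then tests for DE.

## Methods at a glance

With $y_j = \log(\mathrm{count}_j + 1)$ and $x_j$ the GC fraction of
gene $j$ in one lane, the three within-lane procedures are:

* **loess** — robust local regression of $y$ on $x$:
  $y_j' = y_j - \hat y_j + T(y_1,\dots,y_J)$, $T$ = median;
* **global scaling** — genes stratified into $K$ equally sized GC bins
  $k(j)$: $y_j' = y_j - T(y_{j'} : j' \in k(j)) + T(y_1,\dots,y_J)$,
  $T$ = median or upper quartile;
* **full-quantile (FQ)** — count distributions matched across GC bins
  by sorting within bins and taking the rank-wise median across bins
  (the default, and the most aggressive).

Between lanes, counts are either scaled by a single factor per lane
(total count, upper quartile, or median, against a geometric-mean
reference) or full-quantile normalized across lanes. Every
normalization returns integer counts and, via `counts_to_offsets()`,
an equivalent log-scale offset table for use inside a count model.

DE is tested per gene by a likelihood ratio test under a negative
binomial model with variance $\mu + \phi\mu^2$ and a *common*
dispersion $\phi$ estimated by conditional maximum likelihood
($\phi = 0$ recovers Poisson). The evaluation module enumerates all
balanced splits of replicate lanes into two pseudo-groups
($\binom{8}{4}/2 = 35$ for eight lanes), and measures fold-change bias
and MSE, actual-vs-nominal Type I error curves, worst-case envelope
areas, and GC-stratified diagnostics. A seeded simulator generates
counts with library-specific unimodal GC bias, depth differences, NB
over-dispersion, and known true fold-changes.

## Worked example

```r
library(gcnorm)
library(dplyr)

sim    <- simulate_counts(sim_config(n_genes = 2000, phi = 0.078, seed = 1))
counts <- filter_low_counts(sim$counts, sim$meta)          # mean >= 10 rule
feats  <- semi_join(sim$features, counts, by = "gene_id")  # 1990 genes kept

norm <- normalize_within_lane(counts, feats, method = "full", K = 50) |>
  between_lane_fq()

# GC dependence of a cross-library log-ratio, before vs after
lr <- function(cm) log2((cm$lib1_lane1 + 0.5) / (cm$lib2_lane1 + 0.5))
c(raw = gc_lowess_range(lr(counts), feats$gc),
  normalized = gc_lowess_range(lr(norm), feats$gc))
#>        raw normalized
#> 0.67215454 0.02925501

# fold-change bias over all 35 balanced null splits of the 8 lanes
splits <- enumerate_balanced_splits(sim$meta$lane_id)
median(abs(bias_mse_over_splits(norm, splits)$bias))
#> [1] 0.07740943

# NB likelihood ratio test on one null split
grp <- ifelse(names(norm)[-1] %in% splits$group_a[[1]], "A", "B")
fit <- test_de(norm, grp)
glance(fit)
#> # A tibble: 1 × 6
#>   n_genes n_lanes n_groups    df phi_hat n_signif_bh_05
#>     <int>   <int>    <int> <int>   <dbl>          <int>
#> 1    1990       8        2     1  0.0910              1
```

Reading the numbers: the lowess range of the cross-library log-ratio
against GC collapses from 0.67 to 0.03 log2 units (a 96% reduction of
the GC dependence); the median per-gene |bias| across the 35 null
splits is 0.077 log2 units; and on a null split the common dispersion
is estimated near its simulated value with essentially no genes called
DE after BH adjustment — as expected when no DE was simulated.

`tidy(fit)` returns the per-gene table (LRT statistic, p-values,
Bonferroni/BH adjustments); `plot_gc_bias()`, `plot_gc_stratified()`,
`plot_type_i_error()` and `autoplot()` draw the standard diagnostics.
A thin command-line wrapper with `simulate`, `normalize-within`,
`normalize-between` and `de` subcommands lives in
`inst/scripts/gcnorm-cli.R`.

See the vignette in `vignettes/gc-normalization.Rmd` for the full
account of the methods, defaults, and design choices.

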