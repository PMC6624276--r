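# fateinfo

Isogenic bacteria exposed to a lethal antibiotic do not die together: single
cells in the same microcolony can differ by hours in their time of death, and
part of that heterogeneity is forecast by how strongly particular genes
happened to be expressed at the moment the antibiotic arrived. `fateinfo`
quantifies that forecasting power from single-cell time-lapse data, for anyone
studying antibiotic tolerance, persistence, or more generally how stochastic
gene expression predicts single-cell phenotypes.

## The statistic

Each cell carries an initial covariate *y* (reporter fluorescence at *t* = 0,
or cell size, or early growth rate) and a binary state *x_t* (alive/dead) at
every imaging frame *t*. Cells are ranked by *y* and split into *n* = 10
equal-count bins (deciles). The information the covariate carries about fate
at frame *t* is

    I(x_t, y) = H(x_t) - H(x_t | y)

where `H(x_t) = -p log2 p - (1-p) log2 (1-p)` is the binary entropy of the
overall dead fraction *p* at frame *t*, and the conditional entropy is the
unweighted average of the per-bin binary entropies,

    H(x_t | y) = (1/n) * sum_i [ -p_i log2 p_i - (1-p_i) log2 (1-p_i) ]

with *p_i* the dead fraction in bin *i*. For a binary state the statistic is
at most 1 bit: it reaches exactly 1.0 when half the cells are dead and bin
membership determines fate perfectly, and it is 0 when all cells share one
state or when every bin dies at the same rate. The maximum over frames — the
**peak information** — measures how predictive the covariate is; a
**permutation null** (cells regrouped into random deciles, 100 times)
calibrates how large a peak arises by chance from the plug-in estimator's
small-sample bias.

A stochastic simulator generates experiments with known fluorescence–death
links (monotone negative, monotone positive, top-decile threshold, or none)
so the entire pipeline is testable without microscopy data.

## Worked example

```r
library(fateinfo)

ex <- simulate_experiment(sim_config(seed = 42))   # 5 positions x 100 cells
fit <- fate_information(ex)                        # decile bins on fluorescence
summary(fit)
#> Fate-forecasting information analysis ('initial_fluorescence')
#>   500 cells, 10 equal-frequency bins
#>   peak information: 0.3766 bits at t = 135 min
#>   final dead fraction: 1.000; time to 50% death: 110 min
#>   final per-bin dead fractions (bin 1 -> 10): 1.00 1.00 ... 1.00

permutation_test(ex, seed = 7)
#> Permutation test of peak information
#>   observed peak: 0.3766 bits (at t = 135 min)
#>   null (n = 100): mean 0.0246, sd 0.0049, 95% quantile 0.0327 bits
#>   observed exceeds null 95% quantile: yes
```

The simulated reporter carries 0.38 bits about cell fate at its most
informative frame (135 min) — an order of magnitude above the ~0.03-bit peaks
that random decile groupings produce on the same data, so the initial
fluorescence genuinely forecasts when these cells die. `plot(fit, "heatmap")`
draws the per-decile cumulative-death heatmap, `plot(fit)` the information
trace, and `decile_spread(fit$fate_matrix)` summarizes the killing-time
spread between the fastest- and slowest-dying deciles (Savitzky–Golay
smoothed across deciles). `run_analyze()` writes every table as TSV/JSON for
a whole experiment in one call, and `read_cell_table()` ingests real
single-cell tables in the same seven-column CSV layout the simulator writes.

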