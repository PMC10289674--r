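# spikeprec

Estimating the temporal precision of spike-timing codes for continuous
motor output.

Motor units often carry information about movement in the precise timing of
their spikes, on scales finer than the movement itself. `spikeprec` answers
the question *at what timescale does spike timing matter?* for paired data
of the form

* a **spike matrix** `S`: one row per movement cycle (e.g. wing stroke),
  within-cycle spike times in ms, NA-padded to the widest cycle;
* **motor scores** `M`: each cycle's continuous output (e.g. yaw torque)
  projected onto its first two principal components.

It is aimed at neuroscientists with spike-resolved motor (or sensory)
recordings and a rich, non-repeating output — where classic jitter analysis
over repeated stimuli is unavailable.

## The method

The core estimator corrupts all spike times with one-sided uniform noise
`U(0, r_c)` and traces mutual information against the noise width:

    I_c(r_c) = I(S'_c; M) + Σ_i p(S'_c = i) · I(S'_t ; M | S'_c = i)

with `S'_c` the spike count and `S'_t` the corrupted times — the count term
separates rate-code information from the count-conditioned timing terms.
Each term is estimated with continuous k-nearest-neighbour estimators
(Kraskov–Stögbauer–Grassberger, algorithm 1, max-norm, `k = 4`; a
nearest-neighbour mixed discrete–continuous scheme for the count term).
Information is flat while `r_c` is below the code's intrinsic precision and
degrades once noise exceeds it; the **precision** is read off the curve,
by default as the smallest `r_c` whose mean MI (over many noise draws)
falls below the zero-noise MI minus its data-fraction uncertainty. Two
alternative read-off rules (second-derivative peak, two-line intersection)
and a discrete benchmark method (spike-word binning + NSB Bayesian entropy
estimation with shuffling bias correction, precision at the peak of the
corrected MI over bin counts) are included, along with synthetic-data
generators whose ground-truth precision is imposed by rounding, and a
segmentation stage (zero-phase Butterworth band-pass, Hilbert-phase cycle
cuts, per-cycle torque PCA) for starting from raw 10 kHz force/torque
traces.

## Worked example

Generate coupled synthetic data, impose a 2 ms ground truth by rounding,
and estimate the precision:

```r
library(spikeprec)

gen    <- gaussian_pair(n = 2500, rho = 0.9, seed = 1)
spikes <- fix_precision(gen$spikes, 2)      # impose 2 ms ground truth
cfg    <- run_config(n_noise_reps = 10, noise_grid = noise_grid_default(25),
                     seed = 1)

curve <- noise_curve(spikes, gen$motor, cfg)
glance(curve)
#> # A tibble: 1 × 5
#>   zero_noise_mi zero_noise_std n_levels n_reps mi_floor
#>           <dbl>          <dbl>    <int>  <int>    <dbl>
#> 1          1.31         0.0255       25     10   0.0838

precision_from_curve(curve, c("std_threshold", "derivative"))
#> # A tibble: 2 × 3
#>   method        value_ms resolved
#>   <chr>            <dbl> <lgl>
#> 1 std_threshold     2.27 TRUE
#> 2 derivative        1.79 TRUE
```

Reading the numbers: the uncorrupted data carry 1.31 bits about the motor
scores, with an uncertainty of 0.026 bits extrapolated from data fractions.
The mean MI stays near 1.31 bits until the noise width approaches the
imposed 2 ms quantisation, then falls; it first drops below the
1.31 − 0.026 threshold at r_c = 2.27 ms — the precision estimate, within a
grid step of the known 2 ms truth. The derivative rule places the shoulder
of the drop slightly earlier (1.79 ms). At the largest noise widths the
curve approaches the count-only information (here ~0.08 bits, single-spike
data). `autoplot(curve)` draws the curve with the threshold band;
`run_validation()` repeats this recovery over conditions and seeds and
`compare_methods()` summarises each method's error.

A thin command-line wrapper over the same functions is installed at
`inst/cli/spikeprec.R` (subcommands `simulate`, `estimate-continuous`,
`estimate-discrete`, `validate`).

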