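# coopnet — cooperative penalized Cox regression for competing risks

`coopnet` selects variables in high-dimensional survival data with **two
competing events** (e.g. death from disease vs. death from other causes).
It is aimed at biostatisticians analyzing omics-scale covariates (p in the
thousands, n in the hundreds) who currently fit two independent
cause-specific penalized Cox models and thereby ignore effects shared
between the event types.

## The method

For each cause *k*, a Cox model with a feature-weighted elastic net penalty
is fit by minimizing

    (1/n) NLL(β) + λ Σ_j w_j(θ) ( α|β_j| + (1−α)/2 β_j² ),

where NLL is the negative Cox log partial likelihood (competing events
treated as censored, Breslow ties) and the per-feature penalty factors

    w_j(θ) = Σ_l exp(z_l θ) / ( p · exp(z_j θ) )

tilt the penalty according to prior relevance scores z (w_j(0) = 1,
Σ_j 1/w_j = p). The scalar tilt θ is estimated by alternating with the
coefficient step; λ is chosen by the cross-validated partial log-likelihood
(lambda.min).

The **cooperative** part: after initial plain elastic-net fits for both
causes, the algorithm alternates — refit cause 2 with z₂ = |β̂₁|, then
cause 1 with z₁ = |β̂₂| — until the coefficient change falls below ε (or
`mt_max_iter` rounds). Features shrunk to zero for one cause get penalized
harder for the other; shared effects shield each other from shrinkage.

The package also ships the study's synthetic data generators (a
block-correlated n=400/p=5000 genomics design and four low-dimensional
proof-of-concept scenarios), a PPV/FPR selection-scoring harness, and a
small CLI.

## Worked example

```r
library(coopnet)

sim <- gen_highdim_dataset(highdim_config(seed = 2))   # n=400, p=5000
fit <- fit_cooper(sim$data, cooper_config(mt_max_iter = 3, seed = 2))
print(fit)
#> cooper_fit: 3 iterations run, converged = FALSE
#>   cause 1: 7 nonzero (initial 39)
#>   cause 2: 7 nonzero (initial 66)
#>   shared selection: 7 features
```

Scoring the selection against the generator's ground truth
(`classify_selection()` + `compute_metrics()`) for, e.g., cause 2:

```r
beta <- numeric(5000)
nz <- extract_coefficients(fit, 2)
beta[match(names(nz), sim$data$feature_names)] <- nz
compute_metrics(classify_selection(beta, sim, 2))[, c("block","tp","fp","ppv","fpr")]
#>  block tp fp ppv fpr
#>     B1  3  0   1   0
#>     B2  4  0   1   0
#>   B3.1  0  0  NA   0
#>   B3.2  0  0  NA   0
#>     B4  0  0  NA   0
#>  noise  0  0  NA   0
```

Where shared information exists (blocks B1–B2) the cooperative fit selects
7 of 8 true cause-2 features with **zero** false positives across 4 988
noise features. The flip side on this draw: the cause-2-*only* features of
block B3.2 are shrunk away, because the cause-1 model's zeros raise their
penalty — in disjoint-effect blocks the method behaves like (sometimes
slightly worse than) the plain elastic net. That baseline is the same fit's
*initial* step (`extract_coefficients(fit, 2, use_initial_fit = TRUE)`);
here it finds 10 of 12 true features but drags in 56 false positives.

A 10-replicate benchmark (`run_benchmark(design = "highdim", methods =
c("cooper", "coxnet"), n_replicates = 10, base_seed = 1)`) prints medians
(and quartiles) per method × cause × block; in the shared- and
reversed-effect blocks B1–B2 it yields median PPV 90–100% and median FPR
0–0.2% for the cooperative fit versus PPV 21–33% and FPR 3.3–5.5% for the
plain cause-specific elastic net, with both methods near FPR 0.1–0.2% in
the correlated-noise block.

## Command line

```sh
Rscript inst/cli/coopnet.R simulate --design highdim --seed 1 --out data.csv --truth truth.json
Rscript inst/cli/coopnet.R fit --input data.csv --mt-max-iter 3 --seed 1 --out fit.json
Rscript inst/cli/coopnet.R benchmark --design highdim --replicates 10 --seed 1 --out results.csv
```

Every output is accompanied by a `*_config.json` recording the resolved
options and seed; re-running from that record reproduces the artifact
bit for bit.

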