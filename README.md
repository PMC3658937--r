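# pairedbb

Empirical Bayesian analysis of **paired** high-throughput sequencing count
data with a beta-binomial model.

## The problem

Many designs pair two sequencing libraries per biological unit: tumour and
matched normal tissue from one patient, samples before and after
treatment, an epigenetic mark against its input. For each genomic object
("tuple") `c` and sample pair `i` we observe counts `(u_ic, u'_ic)`. Two
kinds of signal matter:

- **within-pair differential expression** — the ratio `u/u'` deviates
  consistently from one-to-one across sample pairs;
- **between-group differential expression** — the ratio differs between
  experimental conditions.

Working conditionally on the pair total absorbs individual-specific
expression levels, which is exactly what pairing is for.

## The model

Conditional on `N = u + u'`, the first count is beta-binomial:

    P(u, u' | Pi, phi) = choose(N, u) * B(u + a, u' + b) / B(a, b)
    a = p (1 - phi) / phi,   b = (1 - p)(1 - phi) / phi
    p = Pi L / (Pi L + (1 - Pi) L')          (library-scaling correction)

with dispersion `phi` in `[0, 1)` (`phi = 0` is the binomial).
Candidate expression patterns are *models*: partitions of the sample pairs
into sets sharing parameters, each FREE or FIXED (e.g. `Pi = 0.5` for a
one-to-one ratio). Per-tuple marginal likelihoods are approximated by
averaging over parameter sets `(Pi, phi)` fitted to tuples sampled from
the whole data set, model priors are estimated by BIC assignment,
posteriors follow from Bayes' rule, and false discovery rates are the
running mean of one minus the posterior down the ranked list.

The package also ships the matching simulator (Poisson counts with beta or
moment-matched Kumaraswamy biological noise, full truth labels) and an ROC
evaluation harness with the exclusion rule needed for fair two-task
comparisons.

## Worked example

```r
library(pairedbb)

sim <- simulate_dataset(n_pairs = 4, n_tuples = 2000, n_within_de = 200,
                        b = 2, seed = 3)
fit <- pbb_posterior(sim$counts, reps = rep("patients", 4),
                     scaling = sim$scaling, theta_size = 100, seed = 3)
fit
#> Paired beta-binomial posterior fit
#>   tuples: 2000  sample pairs: 4  Theta size: 100
#>   priors:
#>     null                 0.8435
#>     consistent_ratio     0.1565

hits <- select_at_fdr(fit$fdr$consistent_ratio, 0.05)
length(hits)
#> [1] 36

roc <- roc_points(de_scores(fit, "within"),
                  positives = sim$truth$tuple_id[sim$truth$label == "WITHIN_DE"])
roc_auc(roc)
#> [1] 0.849975
```

The priors say the BIC assignment attributes ~16% of tuples to the
consistent-ratio model; 36 tuples pass an estimated FDR of 0.05 (2 of them
are truly null in this simulation, a realised rate of 0.056); the
posterior ranks within-pair differential expression with an AUC of 0.85.
`tidy(fit)` returns the per-tuple/per-model table, `glance(fit)` the
one-row summary, `autoplot(fit)` the ranked posterior/FDR curves.

A shell workflow is available through `run_pipeline()` (or the installed
`exec/pairedbb` script): `simulate` writes counts + truth + a config that
`fit`, `posterior` and `evaluate` accept unmodified, each stage leaving a
YAML metadata sidecar with the version, seed and constants in force.

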