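# ordercause

Joint estimation of causal gene-regulatory effects from an arbitrary
mixture of **observational** (wild-type) and **intervention**
(knock-out / knock-down) expression data, under causal Gaussian Bayesian
networks.

Most network-inference tools for expression data either use wild-type
data alone (yielding undirected graphs that cannot orient causality) or
require a complete, systematic single-knock-out design. `ordercause`
targets the realistic middle ground: any combination of wild-types,
partial knock-outs, and multiple (e.g. double) knock-outs, including
designs where some perturbed genes were never measured.

## The model and the method

Each gene follows a linear structural equation with Gaussian residuals,

&nbsp;&nbsp;&nbsp;&nbsp;X<sub>j</sub> = m<sub>j</sub> + Σ<sub>i∈pa(j)</sub> w<sub>i,j</sub> X<sub>i</sub> + ε<sub>j</sub>, &nbsp; ε<sub>j</sub> ~ N(0, σ<sub>j</sub>²),

over an acyclic graph. The **direct effects** are the edge weights
α<sub>ij</sub> = w<sub>i,j</sub>; the **total effects**
β<sub>ij</sub> = ∂E[X<sub>j</sub> | do(X<sub>i</sub>=x)]/∂x are the
entries of L = (I − W)<sup>−1</sup>. A knock-out do(X<sub>J</sub> = 0)
severs the incoming edges of J and fixes those genes deterministically.

Inference runs over **causal node orderings**: for a fixed ordering the
intervention-aware log-likelihood maximizes in closed form over
(m, σ, W) gene by gene, and a Metropolis–Hastings sampler explores
orderings using a **Mallows proposal** (P(O\*|O) ∝ φ<sup>d(O\*,O)</sup>,
Kendall-tau distance, φ = exp(−1/η)) drawn exactly by repeated
insertion. The proposal is symmetric, so a move is accepted with
probability min{exp(ℓ\* − ℓ), 1} where ℓ is the profile log-likelihood.
The temperature η can be auto-tuned to a 30–40% acceptance rate.
Effect matrices are read off the best-likelihood ordering, or averaged
over the sampled ordering posterior.

The package also ships the knock-out simulation benchmark (a bundled
synthetic 10-gene / 21-edge network, five intervention designs, weights
uniform on (−1,−0.25)∪(0.25,1)) and the standard evaluation criteria
(AUROC, AUPRC, Spearman correlation, MSE) for both effect matrices.

## Worked example

Simulate the multiple-knock-out design (10 wild-types, one knock-out per
gene, five double knock-outs) at moderate noise and re-infer the network:

```r
library(ordercause)

dag    <- example_network()                       # bundled 10-gene skeleton
truth  <- random_weights(dag, seed = 1)           # draw edge weights
params <- gbn_params(truth, m = 0.5, sigma = 0.1)
dat    <- sample_gbn(params, benchmark_design("multiple_ko")$design, seed = 1)

fit <- ordercause(dat, n_iter = 20000, burn_in = 2000, thin = 50,
                  eta = "auto", seed = 1)
fit
#> Causal ordering MCMC fit (mallows proposals)
#>   data       : 25 samples x 10 genes
#>   eta        : 0.6 (phi = 0.1889)
#>   schedule   : 20000 iterations, burn-in 2000, thin 50 (360 kept)
#>   acceptance : 28.1%
#>   best loglik: 245.1024
#>   best order : N1 < N6 < N4 < N7 < N5 < N2 < N8 < N9 < N10 < N3

eff <- estimate_effects(fit)                      # best-likelihood estimator
score_effects(total_effects(truth), eff$total, ranking = eff$total_abs)
#> AUROC 0.989 | AUPRC 0.985 | Spearman 0.881 | MSE 0.0321 (36 pos / 54 neg)
```

The fitted chain reports the tuned temperature, the realized acceptance
rate, and the best causal ordering found (here a valid parental order of
the generating DAG, with the global sink N3 last). The score line
compares estimated vs true total causal effects over all off-diagonal
gene pairs: AUROC/AUPRC measure how well true nonzero effects are ranked
above true zeros by |estimate|, Spearman and MSE compare the signed
values. `plot(fit)` draws the node-by-position posterior frequency
matrix; `coef(fit)` returns the estimated direct-effect (weight) matrix.

A thin command-line front end is installed at `inst/exec/ordercause`
(subcommands `simulate`, `run`, `evaluate`).

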