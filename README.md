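# lineagesmc

Bayesian parameter inference for stochastic single-cell dynamics observed on
**lineage trees**.

Time-lapse microscopy tracks every cell of a growing colony and its progeny,
yielding a binary genealogy in which each cell carries a short, noisy
fluorescence time series. Most inference methods treat the single-cell
trajectories as independent, discarding ancestry — exactly the information
that matters when the process of interest acts at cell division (phenotype
switching written at DNA replication) or fluctuates more slowly than a cell
cycle. `lineagesmc` is for researchers in stochastic gene expression and
single-cell systems biology who want to exploit that tree structure.

## The method

For a tree dataset $Y_\mathrm{tree}$ and model parameters $\Theta$, the
package targets $P(\Theta \mid Y_\mathrm{tree}) \propto
P(Y_\mathrm{tree}\mid\Theta)\,\pi(\Theta)$ with two nested Monte Carlo
layers:

1. **Tree-recursive sequential Monte Carlo.** The marginal likelihood is
   accumulated generation by generation over mother–daughter triplets: for
   each of $L$ particles of a mother's division-time posterior, daughter
   birth states are drawn from the division kernel
   $P(x_{n+1}^{2i-1}(0), x_{n+1}^{2i}(0) \mid x_n^i(T_n^i), \Theta)$, both
   daughters are simulated over their lifetimes, and particle $l$ receives
   the weight
   $w_l = P(Y^{2i-1}_{n+1}\mid X^{2i-1,l}_{n+1})\,
          P(Y^{2i}_{n+1}\mid X^{2i,l}_{n+1})$.
   The triplet contributes $\log \frac1L \sum_l w_l$ and the daughters are
   resampled jointly by mother index. Decoupling the branches neglects the
   information daughters carry back about their mother; an exact joint
   particle filter (`tree_loglik_exact`) is included to audit that
   approximation on small trees.
2. **Pseudo-marginal Metropolis–Hastings.** The noisy SMC estimate replaces
   the exact likelihood in an MH sampler (`pmmh`); storing and reusing the
   incumbent's estimate keeps the invariant distribution exactly the
   posterior.

Two model families ship with the package: a two-type **branching process**
(phenotype fixed within a lifetime, redrawn at division from a transition
table with rows $(\theta_1, \theta_2, \theta_2, 1{-}\theta_1{-}2\theta_2)$ /
$(\theta_3, \theta_4, \theta_4, 1{-}\theta_3{-}2\theta_4)$) and a two-state
**CTMC switching model** with correlated lognormal extrinsic noise on the
production rates. Both drive a linear reporter-maturation ODE pair
$\dot D = \alpha(x_d) - (\delta+m)D$, $\dot F = mD - \delta F$ observed as
$y(t_m) \sim \mathcal N(cF(t_m), \sigma^2 F(t_m))$.

## Worked example

Simulate a six-generation tree from the branching process at
$\theta = (0.6, 0.1, 0.1, 0.05)$ and re-infer the transition probabilities:

```r
library(lineagesmc)

set.seed(2)
tree <- simulate_tree(sim_config(branching_model(), n_generations = 6,
                                 lifetime = 30, dt = 5))
tree
#> lineage tree: 127 cells, 7 generations (0..6), 762 readouts

fit <- pmmh(tree, branching_model(),
            proposal = list(proposal_simplex(c("theta1", "theta2")),
                            proposal_simplex(c("theta3", "theta4"))),
            prior = list(theta1 = prior_flat01(), theta2 = prior_flat01(),
                         theta3 = prior_flat01(), theta4 = prior_flat01()),
            init = c(theta1 = 0.25, theta2 = 0.25,
                     theta3 = 0.25, theta4 = 0.25),
            n_iter = 4000, n_particles = 300, seed = 2)

coef(thin_chain(fit, burn_in = 1000, stride = 1))
#>     theta1     theta2     theta3     theta4
#> 0.55819108 0.10533769 0.10578703 0.09108361
```

The posterior means sit close to the generating values — and even closer to
the division outcomes actually realized in this finite tree (63 divisions):
with only a noisy, delayed fluorescence readout per cell, the sampler
extracts essentially all the information the dataset carries about the
division kernel.
`summary(fit)` adds posterior variances, medians and 90% credible
intervals; `plot(fit)` draws traces and posterior densities;
`estimator_convergence()`, `compare_assumption()` and
`compare_tree_vs_trajectory()` reproduce the supporting analyses (particle
sizing, decoupling audit, and the ancestry-vs-trajectory comparison).

A thin command-line wrapper is installed at `inst/cli/lineagesmc`
(`simulate`, `loglik`, `infer` subcommands) for shell pipelines.

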