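# dcmnet

Attractor neural networks learn by turning patterns of activity into stable
states of their own dynamics. `dcmnet` is an R toolkit for studying a
biologically motivated way of doing this in *stochastic* binary recurrent
networks with *asymmetric* synapses: the **delayed-correlations matching
(DCM)** plasticity rule. While an external stimulus field of intensity
λ steps down a staircase, each synapse records the time-delayed correlation
of its pre- and post-synaptic activity at two successive field levels and
moves along the difference,

    ΔJ_ij = η ( ⟨s_i′ s_j⟩_λ − ⟨s_i′ s_j⟩_{λ−δλ} ),
    Δθ_i  = −η ( ⟨s_i′⟩_λ − ⟨s_i′⟩_{λ−δλ} ),

so the recurrent connectivity learns to reproduce the stimulus-driven
dynamics after the stimulus fades. Everything the update needs is local to
the synapse. In the infinite-field limit the rule is an online ascent of the
log-pseudo-likelihood, and at zero noise it reduces to the perceptron rule.

The package is aimed at computational neuroscientists and statistical
physicists who want to reproduce, probe, or extend this family of
experiments. It provides:

* synchronous Glauber dynamics for ±1 and 0/1 units, with a deterministic
  (zero-temperature) limit and an exhaustive fixed-point enumerator for
  small networks;
* the DCM staircase protocol (`present_pattern()`, `train_cyclic()`), the
  clamped-limit/pseudo-likelihood update, and one-shot (palimpsest)
  learning with weight decay;
* classic baselines: Hebb/Hopfield, the covariance (generalized Hebb) rule,
  and Storkey's online rule;
* pattern ensembles: unbiased, biased, sparse, and superpositions of
  features from a finite dictionary, plus corruption utilities;
* the evaluation battery: the corruption-and-retrieval storage criterion,
  maximum-storage-load search, spurious-attractor censuses, palimpsest
  capacity under strict and lax scoring;
* Dale's-principle constrained networks with three effective inhibitory
  feedback schemes (global feedback, soft winner-takes-all, adaptive
  thresholds);
* a minimal restricted visible–hidden architecture with a CD-like
  contrastive clamped-limit update and generative sampling;
* plain-text serialization for couplings and pattern sets, YAML experiment
  configs (`run_experiment()`), and a thin CLI (`inst/cli/dcmnet.R`).

## A worked example

Store ten random patterns in a network of 100 stochastic neurons and check
that every one of them is a retrievable memory:

```r
library(dcmnet)
set.seed(1)

N    <- 100
pats <- iid_patterns(N, 10, seed = 1)          # alpha = 0.1
pars <- dynamics_params(beta = 10)             # low dynamical noise
fit  <- train_cyclic(couplings(N), pats, field_protocol(),
                     learning_params(eta = 1 / N), pars,
                     retrieval_criterion(), max_cycles = 20)

fit$converged
#> [1] TRUE
fit$cycles_used
#> [1] 9
sum(retrieval_test(fit$couplings, pats, retrieval_criterion(), pars))
#> [1] 10
```

Each pattern is presented with a field that fades from 2 to 0 in steps of
0.2; after 9 cycles through the set, all ten patterns pass the strict
criterion — every retrieval from a 10%-corrupted start ends within overlap
0.9 of the memory in at least 90% of attempts. The learned couplings are
asymmetric (`fit$couplings`), unlike the Hebbian baseline, and a
spurious-attractor census (`spurious_census()`) finds far fewer non-memory
fixed points than the same census on Hebbian couplings.

One-shot learning with weight decay — each pattern seen once, never again —
reaches an extensive steady-state capacity:

```r
set.seed(2)
pal <- palimpsest_capacity(100, 60)
pal$capacity_per_neuron          # strict criterion, ~ 0.05 N and above
#> [1] 0.0575
pal$onestep_capacity_per_neuron  # lax single-step stability scoring
#> [1] 0.1332143
```

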