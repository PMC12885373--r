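# pcrbias

PCR amplification bias and what it does to microbiome diversity analyses.

Amplicon sequencing estimates a community's composition through tens of PCR
cycles, and templates do not amplify equally: each taxon has a per-cycle
efficiency `b_d ∈ [1, 2]`, so after `x` cycles the observed ratio of two
taxa is distorted exponentially,

```
w1/w2 = (a1/a2) · (b1/b2)^x .
```

On the simplex this is a clean geometric statement: writing compositions in
log-ratio coordinates `η = Ψ log π` (with `Ψ` a rank-(D−1) zero-sum
contrast matrix), amplification shifts every sample by the same vector
`x·β` with `β = Ψ log b`. `pcrbias` is built around that model and asks the
downstream question: which ecological estimands does this shift move?

* **Perturbation-invariant estimands** — functions of compositions
  unchanged when all samples receive a common log-ratio shift — are immune
  to PCR bias of any magnitude. The differential log-ratio `τ` of
  differential-abundance analysis and the **Aitchison distance** (Euclidean
  distance between clr vectors) are in this class.
* **Perturbation-sensitive estimands** — Shannon, Simpson, Gini, the
  Aitchison norm, Bray-Curtis, weighted UniFrac — are not, and the size
  *and sign* of their bias depend on where the community sits on the
  simplex.

The package provides, for audiences running or evaluating amplicon
workflows:

* the log-ratio algebra (`phi`, `phi_inverse`, `clr`, `perturb`,
  `make_contrast_matrix`);
* a synthetic calibration-experiment generator
  (`simulate_mock_experiment`): multinomial counts over logistic-normal
  compositions shifted per cycle by an efficiency-derived `β`;
* a Bayesian multinomial logistic-normal regression (`fit_mln`) fitted by
  a collapse–Laplace–uncollapse strategy: `(Λ, Σ)` are marginalized
  analytically (the latent `η` then follows a matrix-t prior), the `η`
  posterior is approximated by a Laplace Gaussian at its mode, and joint
  draws of `(Λ, Σ, η)` are regenerated through the conjugate conditionals;
* diversity metrics with posterior bias propagation (`posterior_bias`),
  the invariance classifier (`check_invariance`), ternary bias surfaces
  (`sweep_alpha`, `sweep_beta`), and a worst-case grouping search
  (`optimize_grouping`: exact brute force plus GA and PSO heuristics)
  maximizing `ΔR² = |R²₃₅ − R²₀|` from ANOVA or PERMANOVA.

## Worked example

The `analysis/` scripts run the whole study on simulated data; the same
steps in miniature:

```r
library(pcrbias)

sim <- simulate_mock_experiment(seed = 1)      # 10 taxa, 10 communities,
                                               # cycles 20/28/35, depth 1e4
fit <- fit_mln(sim$counts, sim$design, n_draws = 2000, seed = 2)

beta_hat <- colMeans(extract_alpha_beta(fit, "C1")$beta)
cor(beta_hat, sim$beta_true)
#> 0.9792

posterior_bias(fit, "C1", "shannon", x = 35)$summary
#>  median    lo95    hi95
#> -0.5828 -0.8392 -0.3039
posterior_bias(fit, c("C1", "C2"), "aitchison_distance", x = 35)$summary
#>        median          lo95          hi95
#>  0.000000e+00 -1.332268e-15  1.332268e-15
```

The fitted per-cycle bias tracks the truth (`r ≈ 0.98`); 35 cycles depress
this community's Shannon index by ≈ 0.58 nats with the whole credible
interval clear of zero; and the Aitchison distance between any two
communities is unmoved, to floating point, in every posterior draw. Running
`Rscript analysis/01_simulate.R` … `05_grouping.R` additionally writes
bias tables, ternary surfaces, and the worst-case grouping search — on the
default simulation, optimized groupings shift ANOVA `ΔR²` by 0.66–0.84 for
the sensitive α metrics and exactly 0.00 for the Aitchison distance.

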