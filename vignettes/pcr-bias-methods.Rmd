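---
title: "Methods: modelling PCR amplification bias and its effect on diversity estimands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling PCR amplification bias and its effect on diversity estimands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrbias)
```

## The model

Each template's abundance grows by a per-cycle efficiency $b_d \in [1, 2]$
(1: no amplification, 2: perfect doubling), so after $x$ cycles the ratio
of two templates is $(a_1/a_2)(b_1/b_2)^x$. Only ratios of efficiencies are
compositionally identifiable. In log-ratio coordinates
$\eta = \Psi \log \pi$, with $\Psi$ any rank-$(D{-}1)$ contrast matrix
whose rows sum to zero, amplification is the linear shift
$\eta \mapsto \eta + x\beta$ with $\beta = \Psi \log b$. Natural logarithms
are used everywhere; they make the exponential model exact in $e$-base
units, and all bias magnitudes below are in nats. The additive-log-ratio
basis is the default (the identity block with a $-1$ reference column); an
orthonormal isometric basis is also provided, in which coordinate norms
equal clr norms.

Sequencing observes $\eta$ only through counts. The full hierarchy is

$$Y_n \sim \text{Multinomial}(\pi_n), \qquad \pi_n = \phi^{-1}(\eta_n),
\qquad \eta_n \sim N(\Lambda X_n, \Sigma),$$

where $X_n$ stacks one-hot community indicators and the PCR cycle number,
so $\Lambda$ holds one cycle-0 baseline column $\alpha^{(i)}$ per community
and a single shared per-cycle bias column $\beta$. A calibration design —
the same community sequenced at several cycle numbers — is what makes
$\beta$ identifiable as a slope.

Compositions with zero parts are rejected by the algebra rather than
pseudo-counted; the only zero-handling lives in `read_count_table()`'s
explicit pseudo-count option (0.5 by default when enabled). Round-trip and
unit-sum tolerances are fixed at $10^{-12}$ absolute.

## Inference: collapse, Laplace, uncollapse

`fit_mln()` places a conjugate matrix-normal prior on $\Lambda$ (mean
$\Theta_0$, column covariance $\Gamma_0$, row covariance $\Sigma$) and an
inverse-Wishart prior on $\Sigma$ (scale $\Xi_0$, dof $\upsilon_0$).
Marginalizing $(\Lambda, \Sigma)$ analytically leaves $\eta$ with a
matrix-t prior with column scale $I_N + X^\top \Gamma_0 X$; the collapsed
log-posterior is that density plus the multinomial log-likelihood. The
$\eta$ posterior is approximated by a Gaussian at its mode; each Gaussian
draw is then pushed through the exact inverse-Wishart and matrix-normal
conditionals, giving index-aligned joint draws of $(\Lambda, \Sigma,
\eta)$. Downstream bias estimands always consume $(\alpha, \beta)$ pairs
from the same draw index, preserving their posterior correlation.

Numerical choices:

* warm start from pseudo-count log-ratios $\Psi \log(Y + 0.5)$
  (deterministic, so the mode is independent of the sampling seed);
* L-BFGS with the analytic gradient, then damped Newton polishing until
  the gradient max-norm falls below $10^{-6}$ (non-convergence is a hard
  error with diagnostics, never silent);
* the dense Hessian is assembled by central finite differences of the
  analytic gradient (step $10^{-5}$); at desk scale
  ($D \le 30$, $N \le 100$) this is exact to within the Laplace
  approximation's own error and is reused both for the final Newton steps
  and as the Laplace curvature;
* Cholesky factorization with a small ridge fallback guards
  positive-definiteness.

Prior defaults are $\Theta_0 = 0$, $\upsilon_0 = D + 3$,
$\Xi_0 = (\upsilon_0 - D) I$ (prior mean of $\Sigma$ equal to the
identity), and $\Gamma_0 = 10 I$. The column-covariance scale deserves its
explicit value: a coefficient's prior variance is
$\Sigma_{ll}\, (\Gamma_0)_{jj}$, and with $\Sigma$ fitted near 0.1–0.2 a
unit scale would shrink community baselines estimated from only three
replicates by tens of percent. Because calibration cycle numbers
(20/28/35) never include zero, the baseline and slope covariates are
collinear, and baseline shrinkage leaks directly into $\beta$ — in
simulation it biased posterior-mean $\beta$ by several posterior standard
deviations and visibly degraded interval calibration. A scale of 10 makes
the baseline prior weak relative to the several-nat spread of real
log-ratio baselines while remaining proper; sensitivity between 10 and 100
is negligible.

## What the generator emulates — and what it does not

`simulate_mock_experiment()` mirrors a mock-community calibration study:
10 taxa, 10 communities, one replicate at each of 20, 28, and 35 cycles,
10,000 reads per sample. The calibration cycle numbers {20, 28, 35} are a
declared convention, not an empirical value: three well-spread values
identify the linear-in-$x$ model, and 35 cycles is the evaluation point
everywhere (`x` is a parameter throughout).
Efficiencies are drawn uniformly on $[2 - s, 2]$ with spread $s = 0.3$, so
per-cycle log-ratio biases are small (up to $\ln(2/1.7) \approx 0.16$ per
coordinate pair) but accumulate to severalfold distortion over 35 cycles —
the regime amplicon studies report. Baselines are iid normal with SD 1 in
log-ratio coordinates (several-nat spread, typical of real log-ratio
abundances), and logistic-normal noise is isotropic with variance 0.1.
All randomness flows from one master seed through a documented
stream-splitting scheme (one stream per sample), so partial re-simulation
is stable.

The generator deliberately omits PCR plateau/saturation kinetics, chimera
formation, primer-mismatch effects confined to the first cycles, and any
sequencing error beyond multinomial sampling. Passing tests therefore show
that the inference and the estimand theory behave correctly *under the
exponential-bias model*; they do not show that real libraries contain no
other distortions.

## Diversity metric conventions

Where the literature leaves a choice, the package fixes it:

* **Simpson** means the Gini–Simpson form $1 - \sum p^2$ (bounded in
  $[0,1)$, the common ecology default).
* **Gini** uses the population formula $\sum_{ij} |p_i - p_j| / (2D)$
  without the small-sample correction, so the uniform composition scores
  exactly 0.
* **Shannon** uses natural log, consistent with the package-wide
  convention.
* **Weighted UniFrac** is computed by post-order accumulation of
  descendant mass per edge — $O(D)$ per pair after one traversal — and
  defaults to the normalized variant (raw available via
  `metric_spec(..., normalized = FALSE)`); both variants are cross-checked
  against phyloseq in the tests.
* **Aitchison distance** is computed as the Euclidean distance between clr
  vectors (the $D$-term form). Coordinate-wise definitions in a
  non-orthonormal basis agree with this only up to basis isometry; the clr
  form is basis-free and is the one the invariance theory addresses.

## Bias estimands and the invariance classifier

For an $\alpha$ metric $f$, bias at $x$ cycles is
$f(\phi^{-1}(\alpha + x\beta)) - f(\phi^{-1}(\alpha))$; for a $\beta$
metric both communities receive the same shift. Relative bias divides by
the unamplified value and is an explicit error (not NaN) when the baseline
is below $10^{-12}$. `posterior_bias()` maps these over joint posterior
draws. `check_invariance()` draws $\gamma \sim N(0, 1)^{D-1}$ (scale
configurable), applies the same $\gamma$ to all samples, and classifies an
estimand as invariant when its largest change over the trials stays below
$10^{-9}$ absolute — comfortably above accumulated floating-point error
and far below any real sensitivity, which shows up at $10^{-3}$ or larger.

## Simplex sweeps

Surfaces are evaluated on the lattice $(i s, j s, 1 - (i+j)s)$ with step
$s = 0.01$ by default and a positivity floor of $10^{-6}$ (log-ratio
metrics need strictly positive parts, so the exact boundary is excluded).
Two geometric facts the sweeps make visible required care to state
correctly:

* *Where is Shannon bias largest?* The bias magnitude forms a ring: it
  vanishes toward extreme corners, is locally reduced exactly at the
  barycenter (entropy is stationary there), and peaks at moderately even
  compositions. How much of that ring lies in the strict interior depends
  on the shift magnitude $x\|\beta\|$: at a weak total shift (e.g. 0.7
  nats) the near-boundary band can carry more mean bias than the even
  interior, while at the severalfold distortions real studies report
  (per-cycle $\beta \approx 0.05$, i.e. $\approx 5.7$-fold over 35 cycles)
  the even interior clearly dominates. Tests assert the interior-dominance
  pattern at that empirically relevant magnitude.
* *"Orthogonal" means clr-orthogonal.* The claim that bias in a
  between-community comparison is smallest when the shift is orthogonal to
  the axis separating the communities only holds in the Aitchison (clr)
  inner product; raw ALR coordinates are not isometric and naive
  coordinate orthogonality does not exhibit it. Tests match clr norms when
  comparing parallel and orthogonal shifts.

## Grouping optimization

$\Delta R^2 = |R^2_{35} - R^2_0|$ uses ANOVA $R^2$ (between/total sum of
squares) for scalar diversity values — posterior means per sample — and
PERMANOVA $R^2$ for distance matrices, with the pseudo-F permutation test
counting the observed labelling in both numerator and denominator
(999 permutations by default). Brute force enumerates all
$2^{N-1} - 1$ bipartitions (exact for the $N \le 12$ designs used here);
the genetic algorithm (population 50, 100 generations, tournament 3,
uniform crossover 0.8, per-bit mutation $1/N$, elitism 1) and particle
swarm (40 particles, 200 iterations, inertia 0.72, weights 1.49, positions
thresholded at 0.5) are seeded heuristics kept for fidelity to common
practice; hyperparameters are package conventions. The minimum group size
defaults to 2 so PERMANOVA's within-group sum of squares is defined, and
is applied to ANOVA too for symmetry.

## Problem sizes and determinism

The test suite and acceptance script run everything at the generator's
default scale: invariance over 1,000 trials; one recovery fit plus 20
replicate fits of the 10-taxa × 30-sample design for interval calibration
(2,000 joint draws each); PERMANOVA oracle checks on 10 random instances;
40 heuristic-vs-brute-force runs at $N = 12$; and sweeps at step 0.01
(4,851 grid points). Every stochastic step is driven by an explicit seed,
and the pipeline writes a manifest (config hash plus per-artifact md5) so
reruns are verifiably identical.

## Known limitations

The linear-in-cycles model excludes plateau effects by construction, so
fitted $\beta$ from deep-cycle data averages any late-cycle saturation
into the slope. Presence/absence metrics (Jaccard, unweighted UniFrac) are
out of scope: bias interacts with detection thresholds there and needs an
explicit detection model. The Laplace approximation is accurate at the
depths simulated here (counts in the thousands); at very low depth or with
many zero counts its Gaussian tails understate skewness, and a full MCMC
over the collapsed posterior (as in the Metropolis cross-check in the test
suite) would be the cautious alternative.
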