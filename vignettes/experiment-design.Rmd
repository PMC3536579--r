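---
title: "Fisher-information-driven experiment selection for gene network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fisher-information-driven experiment selection for gene network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fimdesign)
```

## The problem

Ordinary-differential-equation models of gene regulatory networks typically
carry tens of unknown kinetic parameters — production and degradation
rates, Michaelis–Menten-like constants, Hill exponents — that must be
inferred from noisy time-series data. The least-squares cost surface of
such models is *sloppy*: the eigenvalues of the Fisher information span
many orders of magnitude, so some parameter combinations are pinned by the
data while others can drift over orders of magnitude at essentially no
cost. With a single time-series dataset the fitting problem has many
near-degenerate local minima, and the inferred parameters are meaningless.

`fimdesign` implements a greedy, information-driven answer: simulate every
candidate experiment at the current best fit, score each by how much it
would shrink the estimated uncertainty, buy the winner, refit, and repeat.
The package contains the complete machinery: a six-gene network simulator
with forward sensitivities, a synthetic data generator with a calibrated
noise model, penalized Levenberg–Marquardt fitting in log parameters with
multistart search, the information criteria for parameters and for
predictions, the greedy selection loop with a random baseline, and the
cost-landscape diagnostics that justify using local information on a
globally rugged surface.

## The model

The network has six genes; gene $j$ is described by its mRNA and protein
concentrations,

$$\frac{d\,[\mathrm{mRNA}_j]}{dt} = \mathrm{cod}_j - [\mathrm{mRNA}_j],
\qquad
\frac{d\,[p_j]}{dt} = \mathrm{rbs}_j\,[\mathrm{mRNA}_j] -
k_{\deg}\,[p_j],$$

where the mRNA degradation rate is fixed at 1 (it sets the time unit) and
all proteins share one unknown degradation rate $k_{\deg}$. Transcription
of a regulated gene is its promoter strength multiplied by Hill factors of
the regulating proteins, $u/(1+u)$ for activation and $1/(1+u)$ for
inhibition with $u = (x/K)^h$. Gene 1 is constitutive and feeds genes 2, 3
and 4; gene 6 represses gene 2, gene 2 represses gene 3, and genes 4 and 5
form a negative feedback loop that also drives gene 6. Eight edges, each
with its own $K$ and $h$, plus six promoter strengths, six translation
strengths and $k_{\deg}$ give 29 free parameters. The printed equations
use two symbols for the Hill exponent of an edge (one in the numerator,
one in the denominator); the package treats them as a single exponent per
edge, which is the only reading consistent with the 29-parameter count.

Simulations start from the standard initial condition (mRNA 0, protein 1)
and are observed on $[0, 20]$, by which time the system has essentially
reached steady state. The integrator is a stiff-capable adaptive method
(`deSolve`'s `lsoda`) at relative tolerance $10^{-8}$ and absolute
tolerance $10^{-10}$, far below the experimental noise floor; tolerances
are configurable through `solver_control()`. Solver output can carry
negatives of integration-error size; values are clipped at zero when used
as predictions, and clips beyond $-10^{-6}$ warn.

```{r model}
model <- grn_model1()
model
```

### Sensitivities

All information quantities need derivatives of observables with respect to
the *natural-log* parameters (log parameters make positivity automatic and
measure relative uncertainty). The package integrates the forward
sensitivity equations alongside the states in compiled code — exact to
solver tolerance — rather than differencing trajectories. Two compiled
systems back this: the fully augmented system (12 states plus all
12 × 29 sensitivities) under a non-stiff Adams integrator, the fast
path, and 29 per-parameter 24-state systems under the stiff-capable
`lsoda`, which take over automatically when the augmented run hits
stiffness (an implicit solver on the 360-state system would spend its
time factorizing 360 × 360 Jacobians). Central finite differences in log
parameters remain available behind the same interface
(`observation_jacobian(..., method = "fd")`) and serve as the independent
cross-check in the test suite; their default step of $10^{-3}$ balances
truncation error against integrator noise at the default tolerances
(much smaller steps amplify solver noise and are unusable as a default).

## Synthetic data

The generator plays the role of the wet lab. True parameters are drawn
log-uniformly, within [0.5, 2] for the protein degradation rate and Hill
exponents and [0.25, 4] for the production strengths and $K$'s. These
ranges keep the truth well inside the plausible region enforced by the
fitting penalties — the method is being tested on recoverable ground
truth, which is the regime the selection question is about. The procedure
that produced the original challenge's hidden truths is not public;
anything qualitative below is insensitive to this choice, but exact
selection sequences and error tables depend on it.

Observations follow a two-channel noise model,

$$v_{\text{noise}} = \max(0,\; v + C_1\xi_1 + C_2\xi_2 v), \qquad
\sigma_i = \sqrt{C_1^2 + (C_2\, y^{\text{obs}}_i)^2},$$

with $C_1 = 0.1$, $C_2 = 0.2$ and independent standard normal draws per
value. The reported uncertainty is computed from the *noisy* observation,
exactly as the error formula states. A microarray experiment returns all
six mRNA series at 21 evenly spaced times; a protein measurement returns
two protein series at 41 times.

```{r data}
truth <- sample_true_parameters(model, seed = 1)
d0 <- startup_data(model, truth, seed = 42)
head(d0, 3)
nrow(d0)  # 21 time points x 6 mRNA series
```

The candidate catalog crosses 19 perturbations (wild type; deletion,
overexpression, or mRNA knockdown of each gene) with 16 measurements
(microarray or one of the 15 protein pairs), plus one gel-shift assay per
edge: 312 experiments. Deletion zeroes the gene's promoter and RBS
strengths, knockdown multiplies its mRNA degradation rate by 5, and
overexpression doubles its translation rate; all are applied at evaluation
time so the free-parameter list never changes.

The assay is specified in the source material only as an estimate of an
edge's $K$ and $h$. The package represents it as direct observations of
$\log K$ and $\log h$ with Gaussian noise of standard deviation 0.1 in log
space, entering the cost as two extra residuals. This is an
interpretation; the level is configurable (`noise_model(assay_sd = )`),
and with 0.1 an assay contributes variance $10^{-2}$ per constant — on
the scale of the target accuracy, which is why completed designs often
buy several assays late in the sequence.

## Fitting

The cost is half the sum of squared scaled residuals
$r_i = (y_i^{\text{obs}} - y_i^{\text{pred}})/\sigma_i$, augmented with two
penalty residuals $w\theta_\mu$ and $w/\theta_\mu$ per parameter. The
penalties are minimized at $\theta_\mu = 1$, the natural scale; $w = 0.1$
for the degradation rate and Hill exponents (roughly one order of
magnitude of freedom) and $w = 10^{-4}$ for everything else (roughly
eight). They exist to keep the search out of the flat extreme-parameter
regions where the integrator fails, and are weak enough not to move the
final estimates appreciably.

Optimization is Levenberg–Marquardt (`minpack.lm`) over log parameters
with the analytic sensitivity Jacobian. Two numerical choices matter:

* **Stopping.** On sloppy surfaces LM keeps making vanishing progress
  along near-flat directions for thousands of iterations. Fits stop when
  the relative cost reduction per step falls below `ftol = 1e-6` (or the
  relative step below `ptol = 1e-8`, or `maxiter = 300`). Convergence is
  additionally monitored through the angle $\alpha$ between the residual
  vector and the tangent plane spanned by the Jacobian columns: at a
  local minimum the residual is orthogonal to the tangent plane
  ($\alpha \to 90^\circ$), and $|r|\cos\alpha$ estimates the data-space
  distance to the true minimum — the resolution at which two fits can be
  called distinct. These tolerances are recorded in every fit object
  because the distinct-minimum count depends on them.
* **Failures.** Trial points where the integrator fails are treated as
  infinite-cost points so LM can retreat; fits that end on such points
  report `status = "solver_failed"`. Multistart drawing starts
  log-uniformly over the penalty ranges sees such failures routinely at
  extreme corners, and reports them rather than raising.

The geodesic-acceleration refinement of LM used in the original study is
not re-implemented; standard LM with the same residual stack is used,
accepting a lower formal convergence rate. The practical consequence is
that fits stop by the `ftol` criterion at slightly different points along
the flat canyon bottoms — which is exactly why distinctness is measured in
data space rather than parameter space.

## Information criteria

Near a fit, the Fisher information in log parameters is $I = J^\top J$
with $J_{m\mu} = \partial r_m / \partial \log\theta_\mu$ built from the
*data* residuals only (penalties are excluded so the criterion measures
the information content of experiments, not of the prior). The estimated
mean-square log-parameter uncertainty is

$$D_{\text{param}} \approx \tfrac{1}{N}\,\mathrm{tr}\, I^{-1}
= \tfrac{1}{N}\sum_\mu 1/s_\mu^2,$$

where $s_\mu$ are the singular values of $J$ — computed by SVD of $J$,
never by eigen-decomposition of $I$, which matters at condition numbers of
$10^{10}$ and beyond. The calibration is direct: 10% uncertainty in every
direction is $D = 0.01$, 30% is $\approx 0.1$. Natural logs are used
throughout; the same calibration fails in base 10.

Singular values below `rank_tol` $\times\, s_{\max}$ are null directions
and make the estimate infinite. The default is $10^{-12}$: structural
nulls (a parameter with literally no influence on the data, like the
translation strength of gene 3 before any protein-3 measurement) sit at
$\sim 10^{-17}$ relative and are reliably caught, while the merely
ill-conditioned directions that dominate early iterations — where the
criterion legitimately takes enormous finite values like $10^{10}$ —
remain finite and rankable. A tighter threshold (say $10^{-8}$) censors
those to infinity and leaves the early selection rounds with nothing to
rank.

For prediction-targeted design, the same machinery propagates uncertainty
into a target: $D_{\text{pred}} = \tfrac{1}{M}\,\mathrm{tr}(I^{\text{pred}}
I^{-1})$, where $I^{\text{pred}}$ is the Gram matrix of the
$\sigma$-scaled sensitivities of the $M$ predicted values under the
target's perturbed parameters, with $\sigma_m$ from the noise formula
applied to the predicted values. $D_{\text{pred}} = 1$ means the
predictions are uncertain at exactly the experimental-noise level. Null
directions of $I$ that the target does not probe are ignored; null
directions it does probe make the estimate infinite. The built-in default
target predicts proteins 2, 4 and 6 under a strong over-expression of
gene 4 plus milder increases in its feedback loop — an illustrative
stand-in for the challenge's unpublished scoring perturbation, and fully
user-replaceable.

```{r calibration}
d_param_estimate(information_summary(diag(10, 29)))  # 10% everywhere
```

## The greedy loop

Each iteration refits (warm start from the previous best plus a
configurable number of random restarts), simulates all 312 candidates
noiselessly at the best fit, scores them by appending their sensitivity
rows to the current data Jacobian, buys the minimum-D candidate (ties
broken by catalog order), generates its noisy data from the truth, and
records both the predicted score and the value achieved after refitting.
Because one sensitivity solve per distinct perturbation serves every
candidate measurement, a full catalog sweep costs 19 ODE solves, and the
per-iteration cost is dominated by refitting.

Duplicate purchases are allowed by default (a repeat yields a fresh noise
realization and still adds information); completed designs rarely repeat
an experiment.

With the startup wild-type microarray alone the criterion is infinite:
protein 3 regulates nothing, so its translation strength is invisible
until some experiment measures protein 3 — and the first purchased
experiment therefore always includes protein 3. The loop stops at
`stop_D` (default 0.01, i.e. 10% average uncertainty) or `max_iters`.
`random_baseline()` runs the identical loop with uniform-random purchases
for comparison; it typically needs several times as many experiments to
reach the same threshold.

## Landscape diagnostics

The justification for trusting a *local* criterion on a *global* problem
is empirical, and the `diagnostics` functions reproduce it:

* `classify_fits()` splits a multistart ensemble into good and bad fits by
  relative data cost (default: within a factor 2 of the ensemble best).
* `are_distinct()` compares two fits in data space against the
  resolution of the search algorithm: each fit is within
  $|r|\cos\alpha + \sqrt{2\,\mathrm{ftol}\cdot C}$ of its own minimum
  (the convergence-angle bound plus the displacement the relative-cost
  stopping rule cannot resolve), so two fits of one minimum can be up to
  the sum of their resolutions apart. `distinct_minima()` counts connected
  components of the indistinctness graph, which is deliberately robust to
  the non-transitivity of the pairwise relation. The count is
  tolerance-dependent by construction.
* `cost_profile()` evaluates the penalized cost along the straight line in
  log-parameter space between two fits; good-fit pairs on startup data are
  separated by barriers that are tiny compared to the cost at random
  parameters, consistent with one broad basin rather than isolated minima.
* `pca_projection()` and `sloppy_subspace()` extract the dominant spread
  directions of the good-fit ensemble and the least-constrained directions
  of the Fisher information; `principal_angles()` measures their
  alignment. `random_subspace_null()` calibrates the comparison: two
  uniformly random 5-dimensional subspaces of a 29-dimensional space meet
  at a first principal angle of about 49 degrees (SD about 6), so observed
  first angles far below that indicate genuine alignment. PCA and all
  distances are computed in natural-log parameter space, the space the
  optimizer works in; random subspaces are drawn by orthonormalizing
  Gaussian matrices, which is uniform on the Grassmannian. The ambient
  dimension of the null is taken as 29, the free-parameter count.

```{r null}
null <- random_subspace_null(p = 5, ambient = 29, reps = 500, seed = 1)
c(mean = null$mean, sd = null$sd)
```

## A small worked loop

A full design run at publication scale (tens of multistart fits per
refit) takes tens of minutes; the loop below uses a light configuration —
12 initial starts, warm-started refits without restarts — which keeps it
in the minutes range and does not change any qualitative feature.

```{r loop, eval = FALSE}
truth <- sample_true_parameters(model, seed = 1)
hist <- run_design_loop(model, truth, seed = 11,
                        n_starts_init = 12, n_restarts = 0,
                        stop_D = 0.01, max_iters = 20, verbose = TRUE)
print(hist)
d_param_true(hist$final_fit$params, truth)
```

## Problem sizes used by the automated checks

The test suite and the acceptance checks run the same code at reduced
problem sizes, chosen as the package's own defaults for routine
verification: multistart ensembles of tens (not thousands) of starts,
design loops with warm-started refits and no (or few) random restarts, a
handful of random-baseline replicates, and Monte-Carlo nulls with a few
thousand replicates. The qualitative claims they check (infinite startup
uncertainty resolved through protein 3, the threshold being reached within
20 experiments, predictions constrained several times faster than
parameters, random selection needing at least twice as many experiments,
subspace alignment beating the random null) are stable across these
sizes; exact iteration counts and selection sequences are not, and depend
on the sampled truth, the noise realization, and the fit tolerances.

## What the synthetic world does and does not show

The generator emulates the study conditions exactly: known network
topology, known noise law with known constants, single perturbations,
dense regular time grids, and a truth drawn from comfortable parameter
ranges. Real data violate most of these — unknown topology, structured
and non-Gaussian noise, irregular sampling, model misspecification — so
passing tests here demonstrate the internal consistency and the
information-theoretic behavior of the method, not its field performance.
Within the synthetic world, the honest caveats are the ones surfaced by
the diagnostics themselves: the Fisher information is a poor *confidence
interval* when data are sparse (uncertainties extend far beyond the
quadratic approximation), and it is nevertheless an effective *selection
metric*; and the distinct-minimum count is a resolution-limited statement,
not a topological fact.

## Known limitations

* Only the six-gene network is built in; the simulator core is
  model-specific compiled code, and other topologies would need their own
  right-hand sides behind the same interfaces.
* With standard LM, design loops launched from different startup minima
  agree on coarse features — which genes get perturbed, which edges get
  assayed — but not on the exact (perturbation, measurement) sequence:
  early candidate scores come in near-tied clusters, and tiny differences
  in the evaluation point flip individual picks. Likewise, straight-line
  cost profiles between good fits cross high ridges for most pairs (the
  shared canyon winds), and only the closest pairs exhibit barriers far
  below random-parameter cost.
* Standard LM convergence on sloppy problems is slow; fits stop on
  relative-progress tolerances rather than gradient norms, and the
  recorded convergence angle should be consulted when interpreting
  distinctness calls.
* The gel-shift assay noise model and the prediction target are documented
  interpretations of under-specified inputs; both are configurable.
* Estimated-error histories are not monotone: each refit moves the
  evaluation point, and the estimate can jump upward by orders of
  magnitude before collapsing — this mirrors the intended behavior of the
  method, not a defect.
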