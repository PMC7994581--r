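---
title: "Dissociating retrieval and counting strategies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating retrieval and counting strategies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrievalmix)
```

## The scientific problem

Children solving single-digit additions mix two qualitatively different
strategies: direct retrieval of the answer from memory, and counting up
from the larger addend. Observable performance (accuracy, reaction time)
confounds *which* strategy was used with *how efficiently* it was
executed. `retrievalmix` implements a latent process-dissociation model
that separates the two, trial by trial, from choice and reaction-time
data in a verification task, and links training-related changes in the
latent parameters to reorganization of a signed task-based brain
network.

## The two-strategy mixture model

Each trial is a race to one of two absorbing boundaries of a Wiener
diffusion: the upper boundary is the correct response, the lower an
error. A trial by participant $i$ on item $k$ is generated in two steps.

**Strategy selection.** Retrieval is attempted by default; whether it is
pursued depends on the individual's retrieval propensity $\rho_i$ and
the item's group-level retrieval difficulty $\rho_k$:

$$ p(\text{retrieval}) = \frac{1}{1 + e^{-(\rho_i - \rho_k)}},
   \qquad p(\text{counting}) = 1 - p(\text{retrieval}). $$

**Evidence accumulation.** Retrieval accumulates evidence at drift
$\delta^M_{ik} = \delta^M_i / (1 + e^{\rho_k})$: individual efficiency
attenuated by item difficulty, an item-response-style decomposition.
Counting uses the min strategy (count up the smaller addend $n_k$), so
its drift is $\delta^C_{ik} = \delta^C_i / n_k$. Both strategies share
the decision threshold $\alpha_i$ and start unbiased (start point 0.5;
the verification task presents valid and invalid equations equally
often, so no response asymmetry is modelled — the start point is exposed
as a configuration field but fixed by default). Counting is reached only
after abandoning retrieval, which costs the strategy-switching time
$\tau^C_i$ on top of the base non-decision time $\tau_i$; its
non-decision time is therefore $\tau_i + \tau^C_i$.

The trial likelihood is the plain two-component mixture
$$ p_M \, W(t, b \mid \alpha_i, \delta^M_{ik}, \tau_i)
  + (1 - p_M) \, W(t, b \mid \alpha_i, \delta^C_{ik}, \tau_i + \tau^C_i), $$
where $W$ is the defective Wiener first-passage density at boundary $b$.
We deliberately do not truncate or condition the retrieval component at
the switching time: the switching time is modelled purely as a larger
non-decision component of the counting path. This is the simplest
reading consistent with the two-step account, and it keeps the
likelihood a proper mixture (the alternative — a race with explicit
give-up time — changes the retrieval density itself and introduces a
hard non-identifiability with $\tau^C$ at the trial level).

Trial-level strategy attribution is by posterior responsibility,
$p_M L_M / (p_M L_M + (1-p_M) L_C)$. A reaction time below
$\tau_i + \tau^C_i$ is attributable only to retrieval and gets
responsibility 1. The participant-level "retrieval use" summary defaults
to the mean responsibility over valid trials (continuous); a
hard-classification variant (fraction of trials with responsibility
above 0.5) is available via `method = "classify"`, since either
convention is defensible and they can differ at extreme propensities.

### Numerical evaluation of the Wiener density

The first-passage density is evaluated with the adaptive small-time /
large-time series representation, choosing per evaluation the
representation that needs fewer terms for an absolute tolerance of
`1e-10` (user-facing functions) or `1e-8` (inside the sampler, where the
density is evaluated hundreds of millions of times and the Metropolis
ratio is insensitive at that level). The density is zero at and below
the non-decision time by construction, not by error. Boundary masses
use the closed-form absorption probabilities with `expm1` to stay
accurate at small drifts.

The independent check of this density is a path-level simulation oracle:
Euler–Maruyama with step $10^{-4}$ s plus a Brownian-bridge crossing
correction inside each step (the correction removes most of the
$O(\sqrt{dt})$ discrete-monitoring bias; the crossing probability is
only evaluated within ~6 standard deviations of a boundary because it
underflows elsewhere). The same simulator generates all synthetic
behaviour, which keeps the generator independent of the analytic
density it is later used to test.

## Preprocessing rules

Reaction times above 9.5 s are invalid records (the response window) and
are dropped; reaction times strictly below 300 ms are anticipations and
are kept as missing (excluded from likelihoods, treated as missing at
random). The 300 ms rule uses a strict inequality: an RT of exactly
0.300 s is retained.

## Hierarchical estimation

All individual parameters are estimated in one hierarchical Bayesian
model. Retrieval propensity, both efficiencies and the threshold get a
pre-training level and a pre-to-post change per participant, each with
hierarchical normal priors (truncated to keep efficiencies and the
threshold positive at both sessions); the base non-decision time is
shared across sessions with a uniform prior (0.05–1 s); the switching
time has independent uniform (0–2.5 s) values per session, an
equivalent reparameterisation of a level-plus-change pair under flat
priors. Item difficulties $\rho_k$ are shared across sessions ("objective
difficulties") with a hierarchical normal prior whose location is fixed
at zero — the standard item-response anchoring. Without it, a constant
can be traded between all $\rho_i$ and all $\rho_k$ with almost no
likelihood penalty, and the location hyperparameters random-walk
freely; anchoring removes that flat direction.

Location hyperpriors are normal(0, 2); scale hyperpriors uniform(0, 5).
We use independent location hyperpriors rather than a multivariate
normal with an inverse-Wishart covariance: with eight locations
informed by 35 participants the covariance is weakly identified, and
the coupling buys nothing for the quantities reported here while making
a random-walk sampler noticeably less stable. Truncation of individual
parameters is enforced as prior support (violating proposals are
rejected); hyperparameter updates use the untruncated normal terms,
which is accurate because the truncation points lie several prior
standard deviations from the posterior mass at the defaults.

The sampler is an adaptive random-walk Metropolis-within-Gibbs written
in C++: scalar random-walk updates for every individual and item
parameter (proposal scales adapted toward 44% acceptance during
burn-in, frozen afterwards), conjugate Gibbs draws for location
hyperparameters, random-walk updates for scales. Default settings
mirror a production run: 3 chains × 10,000 iterations, 5,000 burn-in,
thinning 1. The reduced `"ci"` profile (3 × 1,000, 500 burn-in) is used
throughout the test suite and the acceptance script; at that budget the
weakly identified hierarchical locations still move slowly (split-Rhat
above 1.1 on some hyperparameters is flagged, not hidden), but the
participant-level quantities the analyses consume — posterior medians
of individual parameters and the joint-model slopes — are already
stable, which is what the recovery checks certify. Convergence is
reported per parameter (split-Rhat, effective sample size by the
initial-positive-sequence estimator) and a fit that fails the Rhat <
1.1 gate is flagged in the returned object and on screen.

Identical seeds give bit-identical draws: each chain's RNG stream is
seeded as `seed + 1000 * chain` and everything stochastic inside the
sampler uses that stream.

## Model comparison

`compare_models()` fits the full mixture, a single-strategy model with
item difficulty, and a plain drift-diffusion model, and ranks them by
WAIC computed from the pointwise log-likelihood of the posterior draws
(accumulated online in the sampler, so no draws × trials matrix is ever
materialised). WAIC was chosen because it is computable from the same
draws for all three models without refitting; the criterion and its
standard error are reported so "ranks first" can be read against
comparison noise.

## The joint brain–behaviour model

The joint model appends a latent regression: the per-participant change
in a brain-network quantity (here the diversity coefficient of the
right rostral hippocampus) is normal with mean
$\beta_0 + \sum_p \beta_p\, \Delta_p$, where $\Delta_p$ ranges over the
five change parameters (propensity, both efficiencies, threshold,
switching time), centered across the cohort at each iteration. The
regression is fitted *jointly*: it feeds back into the participant-level
change parameters, so the slopes are estimated under the latent
uncertainty rather than by a two-stage plug-in. Slopes have standard
normal priors — this is also the reference prior of the Savage–Dickey
Bayes factor, BF$_{10}$ = prior density at zero / posterior density at
zero, with the posterior density estimated by Gaussian KDE
(Sheather–Jones bandwidth) and a moment-based normal approximation
cross-check; both are reported when they disagree by more than 20%.
Evidence labels follow the conventional thresholds (BF > 3 moderate
evidence, 1/3–3 insufficient, < 1/3 evidence of absence). An intercept
is included because the cohort's mean diversity change need not be
zero.

One consequence of joint fitting shapes the pipeline's architecture:
when the behavioural data are weak (few trials per child), the
regression feedback aligns the weakly identified change parameters with
the brain scores themselves, so reading individual parameter estimates
out of the joint fit and then correlating them with those same brain
scores would be circular — the correlation can even come out with an
arbitrary sign. `run_pipeline()` therefore takes all individual
behavioural measures from a behaviour-only fit and uses the joint fit
solely for the slope and Bayes-factor table.

## Signed-network analysis

Task networks are built by psychophysiological-interaction regression:
for each ordered region pair, the target signal is regressed on the
seed signal, the task contrast (+1 addition, −1 control, 0 rest) and
their product; the interaction coefficient is the edge weight, the
matrix is symmetrized by averaging the two directions, and no threshold
is applied. Deconvolution of the seed signal is out of scope here — the
regression runs on the supplied signals directly, so edge weights from
raw BOLD would be attenuated relative to a deconvolved analysis. One
consequence of symmetrization worth knowing: when the two regions have
unequal noise variances the reverse-direction estimate is slightly
attenuated, so a planted interaction of 0.5 is recovered as ≈ 0.45 on
average.

Community detection maximises the signed quality $Q^*$: the
positive-weight modularity minus the negative-weight modularity
down-weighted by total strength, so negative edges inside a module are
penalised asymmetrically. The optimiser is a Louvain heuristic on the
corresponding signed modularity matrix with (by default) 100 seeded
restarts, keeping the best $Q^*$ (ties: fewer modules, then smallest
affiliation vector). On every exhaustively enumerable test instance
(up to 8 nodes, Bell(8) = 4140 partitions) the returned partition
attains the global optimum. Each participant-session matrix is
partitioned independently with the same restart policy — required,
because the reorganization distance is computed between a participant's
own pre and post partitions.

The reorganization distance is 1 − NMI with the symmetric
normalization $2I/(H_1 + H_2)$, chosen because it ranges over [0, 1]
(alternative normalizations by joint entropy or $\log n$ do not change
the qualitative results but rescale the distance). Two degenerate
conventions: two single-module partitions are identical (distance 0);
a single-module partition against a non-trivial one has zero mutual
information (distance 1).

The diversity coefficient of a node is the entropy of its strength
distribution across modules, normalised by $\log m$, computed per sign
channel; the positive channel is the reported one. The node's own
module is included in the entropy — the toolbox convention — even
though the quantity is described in terms of interactions "with other
modules"; excluding the own module would make the measure undefined for
nodes with no external strength. Isolated nodes get 0 by convention.
Node-wise pre/post changes are tested with paired two-sided Wilcoxon
signed-rank tests, Benjamini–Hochberg corrected across nodes, with
optional pooling of bilateral homologues (left/right IPS averaged
before testing, matching how bilateral regions are reported).

## Behavioural statistics

Paired comparisons report the t statistic with both Cohen's d
conventions: $d_z$ (mean difference / SD of differences — the quantity
algebraically tied to t) and $d_{av}$ (mean difference / average of the
pre and post SDs). Published effect sizes for this kind of pre/post
design are frequently inconsistent with $d_z = t/\sqrt{n}$ and imply an
average-variance convention, so $d_{av}$ is the headline value and both
are always printed. Brain–behaviour relations use Spearman rank
correlations (t approximation; exact permutation available for small
tie-free samples). Competing dependent correlations that share an
outcome are compared by a permutation test that swaps the two
predictors within participants, with a Steiger-type z on ranks reported
alongside. The Region × Time repeated-measures ANOVA uses the standard
within-participant error stratification.

## What the synthetic cohort emulates — and what it does not

The generator mirrors the study conditions: 35 children, single-digit
addition verification with operands 2–9 (36 unordered items,
$n_k$ = smaller addend), a 9.5 s response window, 24 scanned trials per
participant and session (recovery studies use 200 — individual-level
recovery from 24 trials alone is not expected, and the hierarchical fit
at 24 trials/session leans correspondingly harder on shrinkage), and
30-node signed networks with two planted modules before training and
three after.

Population distributions were fixed once, a priori, at values a
developmental-cognition study of this design would find realistic:
pre-training retrieval propensity mean −0.5 (children counting more
often than retrieving), a training shift of +0.9 in propensity, a
memory-efficiency gain with standardized size ≈ 2.4 (the defining,
strongest effect of this design), small counting-efficiency and
threshold changes, non-decision time ≈ 0.3 s, switching time ≈ 0.45 s
with a slight training decrease. Network edges are Gaussian around
+0.6 within and −0.2 between modules (noise SD 0.15); the designated
hippocampal node has mildly positive between-module edges (mean 0.09)
so that its diversity has room to move in both directions. The
brain–behaviour coupling plants
$\Delta\text{diversity} = -0.15 - 0.8\,(\Delta\delta^M - \overline{\Delta\delta^M}) + \varepsilon$,
$\varepsilon \sim N(0, 0.1)$, realised exactly by rescaling the node's
between-module strengths under the planted post partition (targets
beyond the reachable entropy range are clipped with a warning). The
−0.15 mean shift makes the node's diversity decrease detectable at the
cohort level; −0.8 is the planted slope the joint model must recover.

What the generator does **not** emulate: hemodynamics and fMRI noise
(edges are drawn directly, not estimated from simulated BOLD),
item-difficulty structure correlated with problem size (difficulties
are exchangeable draws), session-level practice effects other than the
planted parameter shifts, response bias, and contaminant processes
(lapses, fast guesses). Passing tests therefore certify the estimation
and analysis machinery under the model's own assumptions — they do not
certify robustness to model misspecification on real data.

## Problem sizes used by the checks

The test suite and the acceptance script run the reduced MCMC profile
throughout. The recovery study uses the full 35 × 200-trials-per-session
design; the end-to-end pipeline checks use 14 participants × 60 trials;
model-recovery comparisons use ten replicate 8 × 60 cohorts; the
density oracle uses one million simulated paths per parameter set and
the mixture-distribution check 10^5 trials per set. These sizes were
chosen so each check is decisive for the property it certifies while
the whole suite stays comfortably re-runnable.

## Known limitations

* The sampler is a random-walk scheme: posterior medians of individual
  parameters and regression slopes stabilise quickly, but hierarchical
  location/scale hyperparameters mix slowly at reduced settings and
  their Rhat flags should be taken seriously for substantive use.
* The joint model regresses one brain score on five latent changes with
  n = 35; collinearity among latent changes dilutes individual slopes,
  which is the honest behaviour of the design, not a defect of the
  implementation.
* Missing reaction times are assumed missing at random; censored trials
  (no response within the window) are excluded rather than modelled as
  censored observations.
* The two-strategy space is fixed; additional strategies (e.g.
  decomposition) would be absorbed into whichever component fits them
  better.
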