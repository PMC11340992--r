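---
title: "Connectome-based predictive modeling, lesioning, and the synthetic cohort: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling, lesioning, and the synthetic cohort: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conncpm)
```

# Overview

`conncpm` implements an analysis chain common in individual-differences
connectomics: per-participant functional connectivity matrices are summarized
through a connectome-based predictive model (CPM), the resulting network
strength scores are related to biomarkers and cognitive composites with
covariate-adjusted rank correlations, and the anatomical specificity of any
association is probed by computationally lesioning canonical brain networks
and comparing the lesioned and whole-brain associations with Steiger's Z.
Because suitable clinical neuroimaging cohorts are access-restricted, the
package ships a seeded synthetic-cohort generator with planted, analytically
controlled effects; every statistical property the package claims is verified
against that generator or against independent oracles in the test suite.

# Connectome construction and quality control

**Fisher-z connectivity.** Given a node-by-time matrix, every node pair's
Pearson correlation is Fisher-transformed, `z = atanh(r)`. `|r|` is clipped
at `1 - 1e-7` before the transform: a perfectly (anti)correlated pair then
maps to `z ≈ ±8.4`, which is far outside the range of empirical connectivity
(typically `|z| < 1.5`), so the clip changes nothing on realistic data while
keeping all summaries finite. A constant time course is an error (its
correlation is undefined); an all-`NA` time course denotes a node missing
for that participant and propagates as an `NA` row/column.

**Node harmonization.** A node missing (all-`NA`) in at least
`min_participants_missing = 3` participants is removed from every
participant, so the cohort stays on one node list. Nodes missing in fewer
participants are retained; their `NA` edges are simply never selected or
scored for the affected participants. The operation is idempotent and order
matters only through the missingness counts.

**Motion/coverage QC.** Exclusion is applied in narrative order: coverage
or global-signal failures first (a boolean flag in the phenotype table —
image-level detection is out of scope), then mean framewise displacement
strictly above `fd_threshold = 0.15` mm. The boundary is deliberate: a
participant at exactly 0.15 mm is retained. Each excluded participant is
counted under exactly one reason, so the per-reason counts always sum to
`n_in - n_out`.

# The CPM

**Edge selection.** Each upper-triangle edge is Pearson-correlated with the
behavioral score across training participants; edges with two-tailed
`p < threshold` enter the positive ("high") or negative ("low") candidate
network according to the sign of `r`. The default `threshold = 0.01` is
standard CPM practice and is a configuration value, never hard-coded
downstream. Constant edges have undefined correlations and are never
selected, which also keeps the two polarities disjoint by construction.

**Leave-one-out training.** For each left-out participant, selection runs
on the remaining `n - 1`; training-set network strength (mean Fisher-z over
the fold's edges, separately per polarity) is regressed on behavior by
ordinary least squares; the fitted line predicts the left-out participant
from their own strength. The consensus mask is the intersection of the fold
selections. A fold that selects nothing contributes an undefined prediction
and an empty set to the intersection; training fails only if every fold is
empty for both polarities.

Two properties of this scheme are worth knowing. First, adjacent LOO folds
share all but two observations, so fold selections are highly correlated
and the consensus prunes only edges near the significance boundary; with
`n` in the hundreds the consensus size is close to the full-sample
selection, which at `p < .01` includes about 1% of null edges alongside
the true ones. Second, under a permutation null the LOO predicted-observed
correlation is not exactly centered at zero but slightly negative — a
small-sample artifact of selecting and fitting on training sets that
exclude the test point. The bias shrinks with `n` and with more liberal
selection thresholds (about −0.04 at `n = 80` in our null simulations);
the permutation tests therefore use `n = 80` and assert the null mean is
near zero at that scale, while the planted-signal tests require
near-perfect (`> 0.99`) recovery, an unambiguous contrast.

**Strength scoring.** Network strength is the arithmetic mean of a
participant's Fisher-z values over a mask's edges, each unordered edge
counted once. An empty mask has *undefined* strength — reported as an
explicit error or `NA` field, never as zero. A combined high-minus-low
score is available behind `combined = TRUE`; it is an interpretation some
CPM studies report and is off by default.

# Associations

**Partial Spearman.** All variables (predictor, outcome, covariates) are
rank-transformed with average ranks for ties; the partial Pearson
correlation of the ranked predictor and outcome given the ranked covariates
is computed from the inverse of their joint correlation matrix. With no
covariates this is exactly Spearman's rho, and the estimate inherits rank
invariance: strictly monotone transforms of predictor or outcome and
affine transforms of covariates leave it unchanged. Adjustment is
symmetric (both variables are residualized on the covariates); adjusting
only the predictor is a defensible alternative we did not take, because
the symmetric partial correlation is what standard implementations
compute. P-values use `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` on
`n - 2 - k` degrees of freedom, two-tailed, and are reported unadjusted
for multiple testing (recorded in the output metadata). The test suite
checks this implementation against an independent
residualize-ranks-then-correlate oracle to `1e-10`.

**Steiger's Z.** For two dependent correlations sharing one variable
(the outcome against whole-brain strength and against lesioned strength),

$$Z = (z_{jk} - z_{jh}) \sqrt{\frac{n-3}{2 - 2\bar c}}, \qquad
\bar c = \frac{r_{kh}(1 - 2\bar r^2) - \tfrac{1}{2}\bar r^2 (1 - 2\bar r^2 - r_{kh}^2)}{(1 - \bar r^2)^2},$$

with \(\bar r\) the back-transformed mean of the two Fisher z's. Identical
correlations return `Z = 0` exactly even when the covariance term is
degenerate (e.g. the two predictors coincide, `r_kh = 1`). Correlations of
exactly ±1 are an error — no clipping is applied here, unlike in
connectome construction, because a unit correlation among strengths
signals a degenerate comparison rather than a numerical accident. Feeding
rank-based rhos into this normal-theory statistic is an approximation; the
type-I error of the whole construction is verified by simulation (nominal
at α = .05 within binomial error over 2,000 trivariate-normal nulls).

# Computational lesioning

Lesioning a canonical network removes all of its atlas-labeled nodes from
every matrix and deletes every mask edge incident to a removed node —
within-network and between-network connections alike. Strength is then
recomputed as the mean over the *surviving* edges (not rescaled to the
original edge count). The operation is idempotent and commutes across
networks, and the surviving edge set equals the brute-force set difference
(tested exhaustively). The Steiger comparison uses one shared
listwise-complete participant set for all three correlations — the
dependent-correlation test requires a common sample, a detail the
procedure description leaves open — with `r_kh` the unadjusted Spearman
correlation between the two strength scores. A lesion that empties the
mask yields a row of explicit `NA` fields.

One arithmetic note: descriptions of this procedure sometimes quote a
lesioned matrix dimension inconsistent with the stated node counts
(removing 35 nodes from 262 leaves 227). The package does exact
arithmetic and reports the removed-node and surviving-node counts rather
than asserting any fixed dimension.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every statistical claim of the package is validated.

**Generative model.** A standard-normal latent behavior \(b_i\) drives a
set of planted signal edges,
\(z_{ie} = \mu_e \pm \beta b_i + \varepsilon_{ie}\), with per-edge baselines
\(\mu_e \sim N(0.25, 0.15^2)\) (typical resting-state Fisher-z magnitudes),
coupling \(\beta\) (`effect_size`, default 0.1) and noise
\(\varepsilon \sim N(0, 0.2^2)\). Averaging over the \(K\) positive-signal
edges gives an analytic strength–behavior correlation
\(c_s = \beta / \sqrt{\beta^2 + \sigma^2 / K}\), which the copula below
uses to hit rank-correlation targets exactly in expectation.

**Copula.** The biomarker and mean-FD latents form a trivariate Gaussian
copula with the behavior. Planted Spearman targets are converted to latent
Pearson correlations by \(\rho_P = 2\sin(\pi \rho_S / 6)\) and divided by
\(c_s\) to give factor loadings; a target that needs a loading outside
\([-1, 1]\) (weak edge signal, ambitious target) raises an error naming
the offending parameter. The biomarker–FD cross-correlation is planted at
the unique value for which partialling FD out of the strength–biomarker
association leaves it equal to its marginal target — so the pipeline's
motion adjustment is unbiased for the planted effect, and both the
marginal and the adjusted estimate recover the configured rho. Cognitive
composites load on the behavior factor only (one-factor structure,
positive semidefinite by construction).

**Margins.** The biomarker is `scale * exp(skew * latent)` — log-normal,
positively skewed as CSF analyte ratios are, and a strictly monotone
transform, so all rank-based targets are unaffected. Mean FD is log-normal
matched to a mean of 0.0768 mm and SD of 0.0278 mm, the scale of a
well-behaved elderly resting-state sample.

**QC and missingness.** QC failures are assigned as exact counts
(`round(frac * n)`), making cohort accounting deterministic: the default
configuration screens 324 participants, fails 5 on coverage and 30 on
motion, and retains 289. FD-fail participants are chosen uniformly at
random and have their FD resampled above threshold, rather than taking the
upper tail of the FD distribution; this keeps the retained subsample an
unbiased draw so planted correlations survive QC, at the cost of realism
in who precisely gets excluded (real exclusion correlates with true
motion). FD values of passing participants are clamped at the threshold so
the planted failure count is exact. Missing nodes (default: 6 of 268) are
all-`NA` in three to five random participants each, guaranteeing their
removal at harmonization.

**What the generator does not emulate.** Edges are conditionally
independent given the behavior — no spatial autocorrelation, no
community structure, no site or scanner effects, no BOLD temporal
autocorrelation (the optional time-series mode draws i.i.d. Gaussian
samples from the implied node covariance). Passing tests therefore show
the *statistical machinery* is correct and calibrated, not that any
particular empirical effect size will replicate in real imaging data.

**Determinism.** A mandatory seed drives one RNG stream per cohort
(`withr::with_seed`, Mersenne-Twister); identical configuration and seed
reproduce byte-identical on-disk output. Matrix TSVs are written with 17
significant digits and read back with correctly-rounded parsing, so
round-trips are bit-exact.

# Validation study sizes

The shipped validation studies use: exact worked examples for cohort
accounting (324 → 289) and harmonization (268 → 262 nodes); 100 random
tables for the partial-Spearman oracle; 20 random 30-node instances for
the strength and lesion oracles; 200 null cohorts (n = 50, 15 nodes) for
the selection false-positive rate; 2,000 replicates (n = 100) for Steiger
type-I error; 100 replicates (n = 300, 30 nodes) for recovery of a
planted rho of 0.4 within ±0.1; and 6 replicates (n = 250, 24 nodes) for
the lesion-specificity contrast. These sizes give Monte-Carlo error
comfortably below each assertion's margin while keeping the default test
run quick on a laptop.

# Known limitations

* LOO consensus masks are only mildly stricter than full-sample selection
  (see above); k-fold schemes, which prune harder, are out of scope.
* The Steiger statistic pairs rank-based correlations with normal theory;
  it is calibrated in our simulations but is an approximation.
* The generator's planted effects are linear in z-space; real
  edge-behavior couplings need not be.
* Group labels (CN/MCI/AD) are carried through the phenotype table but no
  group-difference analysis is implemented.
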