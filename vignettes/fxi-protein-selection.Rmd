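---
title: "Discovering FXI activity-related plasma proteins with fractional-polynomial LASSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering FXI activity-related plasma proteins with fractional-polynomial LASSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Factor XI is a serine protease of the intrinsic coagulation pathway and an
active drug target: FXIa inhibitors appear to prevent venous
thromboembolism (VTE) without the bleeding risk of downstream
anticoagulants, and animal data suggest FXI also modulates inflammation.
Understanding which circulating plasma proteins track with FXI coagulant
activity (FXI:C, expressed as % of normal pooled plasma and measured by a
modified APTT clotting assay) in VTE patients helps map these roles.

`fxiselect` implements a discovery pipeline for this question on targeted
proteomics data (Olink proximity extension assay, relative NPX units):
given a clinical cohort table and a subjects-by-proteins matrix at two
timepoints (acute VTE event, 12-month follow-up), it selects proteins
associated with FXI:C, ranks them by robustness, runs two prescribed
sensitivity analyses, and characterizes the selected sets by pathway
enrichment and by dense subnetworks of a protein-protein interaction
graph.  Because real cohorts of this kind are access-restricted, the
package ships a synthetic cohort generator with planted ground truth; all
tests and examples run on simulated data.

## The model

For each protein $x$ (NPX scale, possibly negative) the package builds the
conventional fractional-polynomial (FP1) basis on the min-shifted positive
value $\tilde x = x - \min(x) + 1$:

$$z_p = \tilde x^{\,p},\qquad p \in \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\},$$

with $p = 0$ meaning $\ln \tilde x$.  All features are centered and scaled
to unit SD.  The outcome model is an L1-penalized (LASSO) linear
regression of FXI:C on all FP features of all proteins, adjusted for
clinical covariates (sex, age, BMI, transient VTE risk factors,
comorbidities, medication) which enter *unpenalized*.  The penalty path is
solved on a 100-point log-spaced grid from $\lambda_{\max}$ (the smallest
$\lambda$ at which every penalized coefficient is zero) down to
$10^{-3}\lambda_{\max}$; $\lambda_{\text{opt}}$ is the exact minimizer of
the pooled out-of-fold mean squared error under seeded ten-fold
cross-validation (no one-standard-error rule).

A protein is *selected* if any of its FP features has a nonzero
coefficient at $\lambda_{\text{opt}}$.  Selected proteins are ranked by
the **lambda ratio**

$$\mathrm{LR} = \frac{\lambda_{\text{entry}}}{\lambda_{\text{opt}}},$$

where $\lambda_{\text{entry}}$ is the largest $\lambda$ at which any of
the protein's features is active.  LR is scale-invariant, is $\geq 1$ for
every selected protein by construction, and orders proteins by how early
(robustly) they enter the path.  The direction of a possibly nonlinear
association is summarized as the sign of the marginal Spearman correlation
between the raw protein and FXI:C.

## Numerical choices

* **Unpenalized covariates** are handled by Frisch-Waugh-Lovell
  projection: outcome and penalized features are residualized on the
  covariates, the penalized-only problem is solved, and covariate
  coefficients are recovered afterwards.  This is mathematically exact and
  avoids the internal rescaling `glmnet` applies to `penalty.factor`,
  which would distort the $\lambda$ scale that the LR contract depends on.
* **Entry-lambda refinement.**  Grid detection alone limits
  $\lambda_{\text{entry}}$ to grid resolution ($\approx 7\%$ steps).  The
  package refines it by extending the inactive-side KKT gradient line
  $c_j(\lambda) = x_j^\top r(\lambda)/n$ (piecewise linear while the
  active set is fixed) to its crossing with $|c_j(\lambda)| = \lambda$,
  clamped to the bracketing grid interval.  On orthogonal designs this
  reproduces the soft-threshold closed form
  $\lambda_{\text{entry}} = |\operatorname{cov}(x_j, y)|$ to machine
  precision; on general designs it stays within one grid step of a
  dense-grid re-solve.
* **Scale invariance in practice.**  The outcome is internally normalized
  to unit SD and all $\lambda$s rescaled on return, so
  $\lambda_{\text{entry}}$ and $\lambda_{\text{opt}}$ are exactly
  homogeneous in the outcome scale.  Rescaling the outcome by a power of
  two reproduces results bitwise.  For arbitrary factors, residual
  deviations come from the coordinate-descent tolerance amplified through
  the entry refinement of "grazing" features: at `thresh = 1e-12` on small
  designs the worst LR deviation we measure is $\sim 10^{-14}$; at the
  default `thresh = 1e-8` on the full collinear FP design it can reach
  $\sim 10^{-7}$.  The default trades this, invisible at selection level,
  against a threefold runtime reduction.
* **FP input scale.**  The FP basis consumes raw (shifted) NPX values, not
  the normality-transformed ones: the basis performs its own power
  transforms, and double transformation would change the meaning of the
  powers.  The square-root/log normality transforms (chosen per protein by
  minimizing absolute moment skewness over identity/sqrt/ln) are used for
  descriptive statistics and are logged as provenance.
* **Ties and determinism.**  CV folds come from a seeded permutation; the
  seed is a required, logged argument.  Ties in $\lambda_{\text{opt}}$
  resolve to the larger $\lambda$; ties in LR ranking break by protein
  identifier.  Both network algorithms break ties by node identifier, so
  every stage is bit-reproducible.
* **Degenerate inputs.**  Constant protein columns are dropped from the
  basis with a warning; constant columns get the identity normality
  transform; observations missing FXI:C are dropped; missing protein
  values are median-imputed per protein (the motivating study is silent on
  missingness).

## Preprocessing rules

Observations with active malignancy are excluded (cancer's
proinflammatory protein profile would confound), as are observations with
severe FXI deficiency, FXI:C < 20% (boundary: 20.0 is retained).  FXI:C
strata are low < 70%, normal 70-150% (inclusive), high > 150%.  The
descriptive table reports % (n) for binary flags, mean ± SD for
continuous variables with |skewness| ≤ 1, and median (Q1/Q3) otherwise.
The acute versus follow-up FXI:C comparison is a classical paired t-test
on subject-matched values; all-zero differences return t = 0, p = 1,
while zero-variance nonzero differences are an error.

Two sensitivity analyses rerun the full pipeline on subsets: (1) DOAC
non-users (direct oral anticoagulants interfere with APTT-based assays);
(2) excluding observations with normal-or-high FXI:C *and* an elongated
APTT — discordance suggesting assay interference.  The APTT elongation
cutoff is not printed in the motivating literature; the package defaults
to 38 s (a common upper reference bound) and exposes it as a parameter.
Low-FXI:C observations are never dropped by rule (2): a long APTT is
expected there.

## Enrichment and networks

The enrichment query is the selected set plus every measured protein whose
absolute Spearman correlation with a selected protein strictly exceeds
0.80 (absolute, because a strong negative partner is equally informative;
the strict inequality follows the stated rule).  Over-representation uses
the one-sided hypergeometric upper tail $P(X \geq k)$ with the *measured
proteins* as background — not the genome — and raw p < 0.05 with no
multiplicity correction, matching the descriptive intent.  Shared and
timepoint-specific significant pathways are partitioned by set
membership.

Markov clustering (MCL) runs on the column-stochastic transition matrix
of the weighted adjacency with unit self-loops, alternating expansion
(squaring) and inflation (elementwise power 2.0, the canonical default,
then column renormalization) until convergence; clusters are the
connected components of the converged matrix's support.  MCODE weights
each vertex by the density of the highest k-core of its closed
neighborhood times that core number, grows complexes greedily from
unused seeds in descending weight order (admission within 20% of the seed
weight), haircuts each candidate to its 2-core, and keeps complexes of at
least 3 nodes scored by density × size.  Edge weights feed MCL but are
ignored by MCODE (a topological algorithm); density excludes self-loops,
$2|E| / (n(n-1))$.

## The synthetic world

`simulation_config()` defaults encode the dimensions of the motivating
setting: 549 acute observations, 187 follow-up observations all paired
with acute subjects (the overlap rule is exposed as `n_overlap` since
pairing structure beyond "all follow-ups are paired" is not documented),
444 proteins in correlated blocks (size 8, exchangeable ρ = 0.5) so that
high-correlation partners exist; each truly associated protein
additionally receives a designated partner column at Pearson ρ = 0.9 so
the ρ > 0.80 augmentation step has work to do.  FXI:C is built from a
covariate term, planted protein effects (linear, log, reciprocal, or
quadratic shapes applied on the same min-shifted scale the FP basis
uses), a −25% offset for DOAC users (the literature reports lower FXI:C
under DOACs without a magnitude; 25% is a realistic assay-interference
scale), and Gaussian noise calibrated so the proteins explain
`signal_r2` (default 0.5) of the covariate-adjusted variance.  Acute
values are rescaled to mean 120.8, SD 33.79 and follow-up to mean 87.2,
SD 34.3; the antigen proxy attains Spearman ρ ≈ 0.22 with FXI:C via a
Gaussian copula; APTT declines with FXI:C (slope −0.07 s/%); 59.4% of
follow-up observations are flagged DOAC users (exactly 111 of 187 under
the defaults), with exact counts rather than binomial draws so exclusion
arithmetic is testable.  Small planted fractions of active malignancy
(3%) and severe deficiency (2%) exercise the exclusion rules.

What the generator does *not* emulate: PEA plate/batch effects, limits of
detection, missingness mechanisms beyond completely-at-random, skewed
protein distributions (NPX blocks are Gaussian), and longitudinal
trajectories beyond two timepoints.  A green recovery test therefore
establishes that the pipeline finds planted linear and nonlinear signals
under realistic correlation structure and dimensionality — not that it is
robust to assay artefacts.

## Design choices made where the design was open

* **FP1, not FP2.**  All eight conventional FP powers of every protein
  enter as separate penalized features and the LASSO picks among them;
  FP2 product terms are out of scope.  This keeps the design at
  444 × 8 = 3552 features and lets nonlinearity be data-driven.
* **Protein-level aggregation.**  "Protein included in the model" means
  *any* of its transforms is active; the protein's entry lambda is the
  max over its features.
* **Direction for nonlinear effects** is defined as the sign of the
  marginal Spearman correlation, which is monotone-invariant and matches
  what a signed dot plot of selections displays.
* **Exact-minimum CV rule** (not 1-SE), per the stated
  MSE-minimization rule.
* **Antigen as predictor**: off by default; the cohort table carries
  `fxi_ag` so it can be added to the covariate list if desired.
* **Signal scaling**: the planted protein signal is normalized to unit
  variance *after* summing the (possibly correlated) effect columns, so
  `signal_r2` is the protein share of covariate-adjusted outcome variance
  regardless of how correlated the active set is.

## What the recovery tests measure

The parameter-recovery tests report sensitivity (share of planted actives
selected) and a false-selection proportion defined as the share of
*inactive* proteins selected, not counting the designated high-correlation
partner of each active.  The alternative among-selected (false-discovery)
proportion is intrinsically high for the exact-minimum CV rule: LASSO at
the CV-MSE minimizer is known to overselect, and on the recovery world
(n = 500, 100 proteins, 6 actives, signal R² = 0.5) the among-selected
false proportion is around 0.65 for any implementation of this rule.
Users who need a sparser, more conservative list should rank by lambda
ratio and cut deeper, or apply stability selection downstream — both
outside this package's scope.

## Known limitations

* Entry-lambda detection below the grid floor ($10^{-3}\lambda_{\max}$)
  is impossible; proteins entering later are reported unselected with no
  ratio.
* The LR of features that graze the path (KKT line nearly parallel to the
  threshold) is intrinsically ill-conditioned; see the numerical notes.
* No inference is provided on selected coefficients (no standard errors
  or post-selection p-values), and elastic-net or grouped penalties are
  out of scope.
* MCODE "fluff" is not implemented (haircut only), matching the published
  defaults used here.
* The synthetic acceptance world cannot reproduce cohort-specific protein
  identities; recovery criteria are therefore property-based (sensitivity,
  false-selection proportion, null behavior) rather than identity-based.
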