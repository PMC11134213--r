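---
title: "Integrating maternal, placental and cord-serum metabolomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating maternal, placental and cord-serum metabolomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadomics)
```

## The analysis problem

Quantitative NMR metabolomics yields absolute concentration panels —
samples by metabolites — for specimens collected across the
maternal–placental–fetal unit: maternal third-trimester serum (nmol/L),
placenta at delivery (nmol/g) and umbilical cord serum at delivery
(nmol/L). `dyadomics` implements a complete analysis path for asking, in a
cohort of mother–infant dyads, (i) whether two compartments' metabolomes
co-vary beyond what shared covariates explain, (ii) which metabolite pairs
drive that covariation, and (iii) whether the dominant axes of shared
variation are associated with a three-level neurodevelopmental outcome
(typical development TD as reference, autism spectrum disorder ASD, and
non-typical development non-TD).

The stages are deliberately conventional, assembled into one tested,
seeded pipeline:

1. **Cohort construction.** Metabolites identified in fewer than 80% of a
   compartment's samples are excluded (a metabolite detected in exactly
   80% is retained — the rule is *strictly less than*), as are listed
   preparation contaminants. Dyads are formed only when all required
   compartments are present; a mother enrolled through several
   pregnancies contributes only her earliest qualifying one, and an
   infant whose older sibling is already in the cohort is excluded, so
   pregnancies are independent within an analysis.
2. **Pairwise screens.** Midrank Spearman correlations within and between
   compartments, with two-sided p-values from the t approximation and
   Benjamini–Hochberg q-values computed per screen; q < 0.10 is the
   reporting rule. Covariate adjustment uses rank-based linear
   regression (below), again with BH control per screen.
3. **Multivariate integration.** When a screen finds at least one
   significant pair, both blocks are log-transformed, residualized on the
   fully adjusted covariate set, standardized, and fed to canonical-mode
   (optionally sparse) partial least squares. The number of latent
   variate pairs is chosen by leave-one-out Q²; the covariance of the
   first pair is tested against a permutation null; a significant model
   is summarized as a relevance network.
4. **Outcome models.** Multinomial logistic regression of the outcome on
   latent variate scores or single metabolites, reporting exponentiated
   coefficients with Wald intervals and simulated predicted-probability
   curves.

When a screen between two compartments finds nothing at q < 0.10, the
pipeline skips PLS for that pair: integrating blocks that show no
pairwise signal invites overinterpretation of noise.

## Rank-based regression

Covariate-adjusted pairwise associations are estimated by minimizing
Jaeckel's dispersion with Wilcoxon scores,

$$D(\beta) = \sum_i a(R(e_i))\, e_i, \qquad
  a(i) = \sqrt{12}\left(\tfrac{i}{n+1} - \tfrac12\right),$$

where $e_i = y_i - x_i^\top\beta$ and $R(\cdot)$ denotes midranks. The
estimator is consistent and highly efficient under Gaussian errors
(asymptotic relative efficiency ≈ 0.955 against least squares) while
bounding the influence of gross response outliers — a sensible default
for concentration data with occasional extreme values. $D$ is convex and
piecewise linear; we minimize it with damped Newton-type scoring steps
$\tau (X_c^\top X_c)^{-1} X^\top a(R(e))$ from the least-squares start,
with step-halving and convergence at a relative coefficient change below
1e-8. The intercept is the median of the final residuals.

Standard errors use the Koul–Sievers–McKean estimate of the scale
parameter $\tau = (\sqrt{12}\int f^2)^{-1}$, obtained from the density of
pairwise residual differences at zero with a bandwidth equal to the
0.8-quantile of the absolute differences divided by $\sqrt n$ (widened to
the 0.95-quantile when $n/p \le 5$). Three finite-sample corrections
matter in cohorts of this size and were validated on null simulations
during development: the $p$ smallest pairwise differences are discarded
(fitting $p$ parameters manufactures near-zero differences that otherwise
inflate the density estimate), a $\sqrt{n/(n-p-1)}$ degrees-of-freedom
factor, and a Huber-style inflation $1 + \frac{p+1}{n}\frac{1-h}{h}$ with
$h$ the windowed weight fraction. Without them, Wald tests at $n = 60$
with eight covariates rejected a true null at roughly four times the
nominal 1% rate, which in turn produced spurious BH discoveries in null
screens; with them the tests are slightly conservative, which we prefer
for a screening tool. Wald p-values use a t reference on $n - p - 1$
degrees of freedom.

Screens run on the natural concentration scale by default — the rank
machinery is invariant to monotone transforms of either variable, so
this choice affects only the reported slope units; a log-scale switch is
provided.

## Canonical sparse PLS

Let $X$ ($n \times p$) and $Y$ ($n \times q$) be the residualized,
standardized blocks. Per component, NIPALS alternates

$$a \propto \mathrm{soft}(X^\top u,\ k_x), \quad t = Xa, \qquad
  b \propto \mathrm{soft}(Y^\top t,\ k_y), \quad u = Yb,$$

where $\mathrm{soft}(v, k)$ keeps the $k$ largest-magnitude entries of
$v$ and shrinks them toward zero by the $(k{+}1)$-th magnitude; loadings
are unit-norm. Because the updates touch the data only through
$M = X^\top Y$, the inner loop runs on the $p \times q$ cross-product,
and in the dense case ($k_x = p$, $k_y = q$) it is exactly the power
method for the leading singular pair of $M$ — the property the test
suite verifies against an SVD oracle at 1e-8. *Canonical* deflation
regresses each block on its own scores
($X \leftarrow X - t\,t^\top X/t^\top t$, likewise $Y$ on $u$),
modeling a bidirectional relationship: neither compartment is designated
the predictor of the other, which is the right stance for tissues that
plausibly influence each other. Sign ambiguity is resolved by making the
largest-magnitude x-loading entry positive.

Sparsity is used when the dyad count is below the combined width of the
two blocks ($n < p + q$), the regime in which dense loadings overfit; a
single budget applied to both blocks (capped at each width) is tuned on
the first component's leave-one-out Q² over the grid 5, 10, 15, …
Budgets are held fixed across permutations — re-tuning under each
permutation answers a different (and much more expensive) question about
the tuning procedure rather than the observed fit; a config option
exposes re-tuning for sensitivity analyses.

**Component selection.** For component $h$, leave-one-out
cross-validation refits the component on $n-1$ rows, predicts the held
-out row of the current $Y$ residual from its $X$ score, and accumulates
PRESS$_h$; $Q^2_h = 1 - \mathrm{PRESS}_h/\mathrm{RSS}_{h-1}$. Components
are retained while $Q^2_h \ge 0.0975$, the conventional PLS threshold —
the method names Q² but no cutoff is standard-free, so we adopt the
field default rather than invent one.

**Permutation test.** The test statistic is the sample covariance of the
first latent variate pair. Rows of $Y$ are permuted uniformly at random
$B$ times (9999 by default) and the first component refit with the same
budgets; the one-sided add-one estimate is
$p = (\#\{\mathrm{cov}^\pi \ge \mathrm{cov}^{obs}\} + 1)/(B+1)$, with
floor $1/(B+1)$. Permuting after residualization preserves the covariate
structure under the null. Size and power were checked by simulation
(200 null replicates; planted-factor alternatives), and the null
p-value distribution is super-uniform up to permutation discreteness.

**Variance explained.** The proportion reported for a component is the
squared Frobenius norm of the rank-one reconstruction from that
component's scores over the squared norm of the preprocessed block, and
the "pair" value averages the two blocks. Published analyses of this
kind rarely state which functional they report; ours is stated here and
in the function documentation, and no claim is made that it coincides
with any particular publication's convention.

**Relevance network.** With reference variates
$z_h = (t_h + u_h)/2$ — the symmetric choice matching canonical mode —
the similarity between metabolite $i$ of $X$ and metabolite $j$ of $Y$
is $s_{ij} = \sum_h \mathrm{cor}(x_i, z_h)\,\mathrm{cor}(y_j, z_h)$.
Edges connect only nodes from different blocks, carry the sign of
$s_{ij}$, and are kept where $|s_{ij}|$ meets a threshold (default 0.5,
configurable; thresholded network figures in the literature rarely
publish their cutoff).

## Outcome models

The three-class outcome is modeled by multinomial logistic regression
with TD as reference, fit by full Newton–Raphson with step-halving (the
log-likelihood is non-decreasing across iterations) and covariance from
the inverse observed information. Exponentiated coefficients are
reported with the customary "relative risk" label although they are
relative risk *ratios* of a multinomial logit; the distinction is noted
wherever they are printed. Quasi-complete separation — a real hazard
with a small non-TD class — is detected (any fitted probability within
1e-8 of 1) and flagged in the output rather than silently regularized.

Predicted-probability curves propagate estimation uncertainty by drawing
coefficient vectors from a normal centered at the estimates with the
fitted covariance. Probabilities are averaged over the observed
covariate values of the analysis sample (not evaluated at covariate
means), which answers the population-averaged question and behaves
sensibly with binary covariates; the averaging rule is recorded in the
output's metadata. Metabolite predictors enter as z-scores of natural-log
concentrations by default, so RRs are per SD of log concentration; a
raw-scale option exists because published tables of this kind often do
not state their scale.

## The synthetic cohort generator

No raw metabolite data are deposited for cohorts of this design, so the
package ships a generator that emulates the statistical structure the
analysis assumes, with recorded ground truth. On the natural-log scale,

$$\log C_b = \mu_b + L_b F^\top + Z \Gamma_b + E_b,$$

per compartment $b$: intercepts $\mu_b \sim N(\log 100, 1)$ (medians
around 100 nmol/L, the range of ketone bodies and amino acids in serum),
shared latent factors $F$ drawn independent standard normal per block
pair, sparse loadings $L_b$ (a configurable fraction of zeros; nonzero
entries of magnitude near the factor strength with random sign),
covariate effects $\Gamma_b$, and Gaussian noise. Concentrations are the
exponentials — positive and right-skewed, as NMR panels are; the
rank-based screens are invariant to this marginal choice.

Defaults are fixed once as the study conditions and not revisited: 107
dyads; 48/54/44 metabolites for maternal serum, placenta and cord serum;
one latent factor shared between placenta and cord serum and none for
the maternal pairs (the two delivery-time compartments co-vary, the
third-trimester serum does not); loading sparsity 0.5; factor strength 1
against residual SD 0.5 on the log scale; covariates of the types a
pregnancy cohort records (binary indicators at rate 0.5, birth year
uniform over six years, gestational age normal with SD 10 days, fasting
time gamma with median ≈ 80 min); mild planted confounding (metabolic
condition shifting 20% of each block by 0.3 log-units, gestational age
0.1 per 10 days); outcome base rates 57/30/13% for TD/ASD/non-TD; and an
outcome model with log-RR of log 2 on the shared factor for non-TD and 0
for ASD, mirroring the qualitative finding such cohorts report. A "null"
variant removes every shared factor for FDR and permutation size checks.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: spectral overlap and quantification error
correlated across metabolites, detection limits that censor (rather than
randomly delete) low concentrations, batch structure, non-Gaussian
factor distributions, and outcome misclassification. Tests built on it
validate the statistical machinery, not any biological claim.

## Numerical choices and degenerate inputs

- NIPALS convergence: loading change below 1e-10 (1e-9 inside
  leave-one-out and permutation refits), with a 5000-iteration cap and a
  convergence flag; an all-zero loading after thresholding is an error.
- Rank regression: convergence at relative coefficient change 1e-8; a
  step that cannot reduce the dispersion even after halving to 1e-6
  terminates at the (kink) minimum.
- Newton multinomial fitting: tolerance 1e-10 on the step, 200-iteration
  cap, step-halving on the log-likelihood.
- Constant columns: an error in `center_scale()` and
  `metabolite_outcome_screen()`; flagged and excluded from the FDR
  family in screens.
- Non-detects: never imputed. Screens use pairwise-complete
  observations (minimum 5); PLS and outcome models use complete rows.
  Zeros are treated as missing on the log scale. Whether a Chenomx-style
  zero is a true zero or a censored low value is not decidable from the
  data; both interpretations are exposed via the transform switches.
- Ties: midranks throughout.
- Seeds: every random stage of `run_pipeline()` consumes a child seed
  derived from the master seed, and each stage's seed is logged, so any
  single stage can be reproduced in isolation. Identical config and seed
  give bit-identical summary JSON.

## Problem sizes used in the test suite

The statistical guarantees are exercised at sizes chosen to make the
Monte-Carlo assertions sharp while keeping the suite quick to run:
PLS–SVD agreement on 50 random 30×10 / 30×8 block pairs; permutation
size on 200 null replicates at n = 60, p = 20, q = 15 with B = 199;
power and the tri-compartment qualitative pattern on 100 and 50
replicates at n = 60 with 10–12 metabolites per block; BH agreement on
1000 random p-vectors and empirical FDR on 200 null screens; rank
regression on 40 replicates at n = 1000 plus 200 outlier-contaminated
replicates at n = 100; multinomial recovery on 30 replicates at
n = 2000. The acceptance script runs the full pipeline once at the
generator's default scale (107 dyads, 48/54/44 metabolites, B = 9999).

## Known limitations

- The variance-explained functional is one of several in circulation;
  comparisons across software should check definitions first.
- Q² with leave-one-out is noisy for n below ~30; the 0.0975 threshold
  is a convention, not an inference.
- The Wald intervals of the multinomial model are poor under separation
  or very small cells (the non-TD class in realistic cohorts); the
  separation flag should be checked before quoting intervals.
- The rank-regression τ̂ corrections keep test size slightly
  conservative at n/p ≈ 7; very small n/p ratios remain outside the
  validated regime.
- Relevance-network similarities can marginally exceed 1 in magnitude
  with several correlated components; single-component networks are
  bounded by construction.
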