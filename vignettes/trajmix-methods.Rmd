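---
title: "Modelling latent neurocognitive trajectory classes with trajmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling latent neurocognitive trajectory classes with trajmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The model

`trajmix` studies heterogeneity in longitudinal neurocognition among older
adults ageing with HIV. The indicator variable is the *global peak-age
T-score*: the average, across a seven-domain neuropsychological battery, of
demographically adjusted T-scores in which age 25 is substituted for
chronological age in the normative regression. A peak-age T of 40 means
performance one standard deviation below the mean of 25-year-olds of the
same education, sex and race/ethnicity. Peak-age scoring deliberately does
*not* absorb age-related decline into the norms, so decline remains visible
in the trajectories, while other demographic influences are removed.

Trajectories over $J$ six-month visits are modelled as a $K$-class growth
mixture. For participant $i$ in class $k$ at visit $t \in \{0, 1, \dots\}$:

$$y_{it} = (\alpha_{0k} + b_{0i}) + (\alpha_{1k} + b_{1i})\,t +
  \alpha_{2k}\,t^2 + \varepsilon_{it},$$

with $(b_{0i}, b_{1i}) \sim N(0, \Psi)$ and
$\varepsilon_{it} \sim N(0, \sigma^2)$, both shared across classes, and
mixing proportions $\pi_k$. Marginally, a class-$k$ trajectory vector is
multivariate normal with mean $\Lambda \alpha_k$ (columns of $\Lambda$:
$1, t, t^2$) and covariance $Z \Psi Z' + \sigma^2 I$ (columns of $Z$:
$1, t$).

Key modelling conventions, each an explicit design choice:

* **Time coding.** Visit index $t = 0, \dots, 9$ (6-month units). The
  intercept is baseline level; slopes are per-visit changes. On this scale
  class mean slopes of a few tenths of a T-point per visit are typical.
* **Random effects** act on the intercept and linear slope only; the
  quadratic factor mean varies by class but carries no random effect. This
  is a common identification choice for mixtures with moderate $J$, and it
  keeps the shared covariance $\Psi$ a 2x2 matrix.
* **Equal variances across classes.** $\Psi$ and $\sigma^2$ are shared, so
  classes differ only in their growth-factor means. This also removes the
  classic unbounded-likelihood degeneracy of location-scale mixtures.

## Estimation

The observed-data log-likelihood is evaluated by full-information maximum
likelihood: participant $i$ contributes the marginal normal density of the
visits actually observed,
$\log \sum_k \pi_k\, \phi\!\left(y_i^{\mathrm{obs}};
(\Lambda\alpha_k)^{\mathrm{obs}}, \Sigma^{\mathrm{obs}}\right)$, which is
unbiased under missing-at-random dropout. Participants sharing a
missingness pattern share the Cholesky factor of
$\Sigma^{\mathrm{obs}}$, so the cost per EM iteration is linear in $n$.

The EM iteration is closed-form throughout. The E-step computes class
posteriors $p_{ik}$ and the conditional moments of the random effects
given class and observed data; the M-step updates $\pi_k$ and $\alpha_k$
by posterior-weighted generalized least squares and $(\Psi, \sigma^2)$
from the expected complete-data sufficient statistics. The observed-data
log-likelihood is non-decreasing by construction; the package asserts this
on every run and stores the trace.

Numerical safeguards: $\Psi$ is ridged (with a logged note) when its
condition number degrades; $\sigma^2$ is floored at $10^{-10}$; a class
whose posterior mass falls below $10^{-4}$ marks the start as degenerate
rather than returning a spurious optimum.

**Multi-start strategy.** Mixture likelihoods are multimodal. Starting
values come from k-means on per-participant ridge least-squares growth
coefficients; subsequent starts perturb class means and mixing weights.
All starts run a short first stage (default 30 iterations), the most
promising are run to convergence (absolute log-likelihood change below
1e-6, cap 2000 iterations), and the convergence record notes whether the
best log-likelihood was replicated by at least two starts — the standard
guard against local maxima. Classes are relabelled in descending-intercept
order, so "class 1" is always the highest-performing class.

Standard errors come from the numerically differentiated observed
information over all free parameters (growth means, log-Cholesky of
$\Psi$, log residual SD, multinomial-logit mixing weights). They are plain
ML information-based SEs; robust (sandwich) SEs are out of scope.

The `latent-basis` growth option frees the interior slope loadings
(anchored 0 and 1 at the first and last visit) and is estimated by direct
quasi-Newton maximization; it is available for single-class base-model
comparison only, which is where that curve shape is normally used.

## Class enumeration

`enumerate_classes()` fits $K = 1, \dots, K_{\max}$ and tabulates
log-likelihood, AIC, BIC, sample-size-adjusted BIC
($-2\ell + p \ln((n+2)/24)$), relative entropy
$1 - \sum_{ik} (-p_{ik} \ln p_{ik}) / (n \ln K)$ (NA at $K = 1$), the
Lo–Mendell–Rubin comparison with the $(K-1)$-class fit, modal class
counts, and adequacy flags (every class at least 25 members and 5% of the
sample).

**The LMR test.** The likelihood-ratio statistic for $K$ vs $K-1$ classes
is not chi-square distributed — the smaller model sits on the boundary of
the parameter space. The package shrinks $2\Delta\ell$ by the small-sample
factor $c = 1 + ((p_K - p_{K-1}) \ln n)^{-1}$ and refers it to a
chi-square with $2(p_K - p_{K-1})$ degrees of freedom, the long-standing
"two-times" rule for mixture likelihood-ratio statistics. A 200-replicate
null simulation in the test suite confirms the resulting test is
nominal-to-conservative at the 5% level; `bootstrap_lrt()` provides a
parametric-bootstrap cross-check free of the analytic approximation.
Model selection in the pipeline encodes one reproducible default — the
smallest adequate $K$ whose $(K+1)$-class alternative fails the LMR test
at 0.05 — while `select_class_solution()` is overridable because real
enumeration also weighs interpretability and parsimony.

A secondary analysis, `drop_baseline_refit()`, refits the chosen $K$ on
follow-up visits only (original time codes preserved) and cross-tabulates
modal memberships, to verify that class structure is not an artifact of
the baseline indicator also being used for baseline status classification.

## Norming, classification, reserve

`fit_norms()` fits linear main-effects regressions of raw score on age,
education, sex and race/ethnicity in a normative sample; the functional
form of published norms is more elaborate, but a linear form keeps
recovery testable and is stated as a package convention. The fit refuses
rank-deficient designs and normative samples missing a stratum needed
downstream, rather than silently extrapolating. Practice effects are an
additive visit-indexed gain estimated from a retest sample
(`estimate_practice()`); gains beyond the estimated range reuse the last
value, reflecting saturation of practice benefit.

Baseline status uses two rules in sequence: SuperAger requires peak-age
global T at or above 40 *and* every domain T at or above 40 on
chronological-age norms ("within normative expectations" is read as a
closed bound, and "isolated impairment" as any domain below 40);
otherwise the global deficit score (stepwise bands: T >= 40 scores 0, one
point per 5-T band below, capped at 5) classifies impairment at the
conventional 0.5 cutoff. The deficit-score bands and cutoff come from the
cited deficit-score literature, since the source analysis does not print
them, and both are arguments.

The physiologic reserve index dichotomizes 39 health variables against a
versioned rules table (`inst/extdata/reserve_criteria.csv`) and returns
the fraction of available items scored normal. Printed inequalities are
read literally as strict, so boundary values are normal except the one
inclusive bound (triglycerides >= 150 mg/dl). Sex-specific cutoffs (MCHC,
hemoglobin, HDL) dispatch on recorded sex; hypertension is a composite
(diagnosis flag OR systolic > 130 OR diastolic > 85); hemoglobin cutoffs
are kept in the units of the source table (printed umol/l) with a
documented note, since recoding to conventional g/dl would change the
rule. Missing items leave both numerator and denominator.

## The three-step covariate analysis

Class membership is fixed by modal assignment *before* covariates enter,
so predictors cannot reshape the classes (ties, which occur with
probability zero in continuous data, break toward the lower class index
and are logged). Univariable screening dispatches ANOVA for continuous
variables, Kruskal–Wallis for variables declared skewed (symptom counts,
CD4), and chi-square or Fisher's exact test (sparse cells) for
categoricals, selecting predictors at p < 0.10. The multinomial logit
uses the highest-performing class as reference; WRAT4 and the reserve
index are entered per sample SD (so odds ratios read "per 1-SD-unit"),
age and symptom counts raw. Backward pruning removes, one per pass, the
covariate whose best class-contrast p is largest and at least 0.10. The
simpler bias-uncorrected three-step variant is intentional; BCH/ML
weighting corrections are out of scope.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions end to end: 184
participants by default, 10 six-month visits, three latent classes with
quadratic mean growth. The class means default to the published estimates
— (49.62, 0.04, 0.04), (41.91, −0.45, 0.07), (34.22, −1.04, 0.12) — and
the class proportions to 31/184, 100/184, 53/184. Baseline covariates
follow the published descriptives (age 52.9 ± 3.9, education 13.1 ± 2.6,
WRAT4 93.5 ± 15.4, 82% male, race/ethnicity mix, CD4 distributions,
symptom counts as negative-binomial). Class membership is drawn from a
multinomial logit on age, PAOFI count, latent physiologic reserve (per
SD) and WRAT4 (per SD), with slopes equal to the logs of the published
odds ratios and intercepts calibrated at generation time so marginal
class shares match the target proportions. Dropout is monotone and
missing-at-random, driven by education (negative) and enrollment date
(positive) on the logit scale, with visit 0 always observed; intermittent
missingness is available behind a flag.

Within-class variance components are not identified by any published
summary. The defaults — random intercept SD 4, random slope SD 0.3,
residual SD 4 — were chosen once to give a realistic visual spread of
individual trajectories around the class curves and are stated as package
defaults, not published values. A consequence worth knowing: at these
values the classes overlap substantially (relative entropy near 0.55,
lower than the strong separation the motivating study reports), so at
n = 184 the enumeration rule sometimes prefers fewer than three classes,
and *modal* class shares are biased toward the large middle class even
when the model is evaluated at the true parameters (applying the true
parameters to a large simulated cohort gives modal shares roughly
14.7/58.3/27.1 for true 16.8/54.3/28.8). The fitted mixing proportions
$\hat\pi_k$ are the unbiased estimator of class shares, and recovery
checks therefore target $\hat\pi_k$, not modal counts.

Raw domain scores are generated consistently with a known normative
regression (so norming can be tested by exact recovery) plus a practice
gain schedule; between-domain scatter is centred within each visit so the
across-domain mean reproduces the global score exactly. The 35 non-HIV
reserve items are Bernoulli deficits tied to a latent reserve level; the
four HIV items (current/nadir CD4, viral load, disease duration) come
from their own clinical distributions, which leaves the realized index
mean near 0.70 with SD near 0.10, matching the published descriptives.
The generator does not emulate individual test items, site effects, or
informative (MNAR) mortality-driven dropout — so passing recovery tests
says nothing about robustness to MNAR missingness in real data.

## Problem sizes and what the tests show

Parameter-recovery tests use cohorts of 4,000 (growth parameters; a
3-class 40-start EM fit takes a few minutes) and 20,000 (odds ratios);
the LMR null calibration uses 200 replicates of n = 150 with 6 visits and
deliberately capped EM effort per replicate, which changes the
likelihood-ratio statistic negligibly (about 0.05 log-likelihood units)
while keeping the simulation fast. Analytic oracles (numerical
integration for FIML, closed forms for information criteria, hand-coded
rule tables for the reserve criteria and deficit bands) pin down exact
behavior at small scale. What the suite demonstrates is internal
correctness and recoverability under the generator's assumptions — not
performance on the real cohort, whose data are request-only.

## Known limitations

* Robust (sandwich) standard errors and class-specific variance
  structures are not implemented.
* The LMR reference distribution is an approximation; for publication
  grade enumeration decisions the bootstrap LRT is the safer instrument.
* Covariates are generated independently of trajectory residuals given
  class, so the three-step analysis has a clean truth; real cohorts need
  not satisfy this.
* The auxiliary-variable device for missingness correlates is reporting
  plus MAR-valid FIML rather than a saturated-correlates joint model; the
  missingness drivers (education, enrollment date) are measured and
  reported by `missingness_correlates()` so their MAR plausibility can be
  inspected.
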