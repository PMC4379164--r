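---
title: "Methods: paired differential expression and ratio-based LDA classification"
author: "ctratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired differential expression and ratio-based LDA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctratio)
```

`ctratio` implements a two-phase biomarker study design: a discovery phase
on paired microarray expression data, and a validation/prediction phase on
a targeted qRT-PCR panel, ending in a ratio-feature linear discriminant
classifier evaluated on blinded samples. This vignette documents the
statistical models, the tunable parameters, the synthetic-data generators
used for testing, and the numerical and design choices made where the
procedure admits more than one reasonable implementation.

## The paired moderated t-test

Raw intensities $x$ are transformed as $\log_2(x + 1)$ (the offset of one
cycle-equivalent keeps zero intensities finite) and quantile-normalized:
each column's sorted vector is replaced by the across-column mean of
sorted vectors, preserving within-column ranks. Tied entries receive the
mean of their tied quantile slots, which makes the normalized column a
function of the ranks alone; this differs from interpolation-at-average-rank
conventions when three or more values tie, and is the contract our tests
enforce against an explicit rank-expansion oracle.

For gestational-age-matched pairs, the analysis is a one-sample moderated
t-test on within-pair differences $d_{gp}$ (case minus control, log2
scale). For complete pairs this is algebraically identical to a blocked
two-factor linear model and considerably easier to verify. Writing
$\bar d_g$ for the mean difference ($\mathrm{logFC}$), $s_g^2$ for the
sample variance with $d = n-1$ degrees of freedom, empirical-Bayes
moderation shrinks $s_g^2$ toward a prior:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  t_g = \frac{\bar d_g}{\sqrt{\tilde s_g^2 / n}} \sim t_{d_0 + d}.$$

The prior $(d_0, s_0^2)$ is fitted by the closed-form method of moments on
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$: $d_0/2$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)$ (trigamma inversion by
Newton iteration, tolerance $10^{-10}$), and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the trigamma
equation has no positive root (observed variances no more dispersed than
chi-square sampling noise allows), the prior is degenerate: $d_0 = \infty$
and every feature uses $s_0^2$. The limits are exposed for verification:
forcing $d_0 = 0$ reproduces the ordinary paired t exactly, $d_0 = \infty$
the fully shrunk statistic. Zero-variance features are excluded from the
moment fit but still shrunk; a matrix in which *every* feature has zero
variance is an error.

Selection uses strict thresholds, nominal $p < 0.05$ and fold change
$> 1.5$. Fold change is reported signed,
$\mathrm{sign}(\mathrm{logFC})\cdot 2^{|\mathrm{logFC}|}$, a minus sign
marking lower expression in cases. Probes are deliberately *not* collapsed
to genes before testing; gene collapsing happens only when counting unique
genes in a selection. The choice of a nominal rather than FDR-adjusted
cut-off reflects the two-phase design: a downstream targeted confirmation
experiment on new samples controls the false positives, so the discovery
phase favours sensitivity.

## Gene-set scoring with overlap down-weighting

Genes shared by many sets dilute set-level signal. With $f(g)$ the number
of sets containing gene $g$, the weight

$$w(g) = 1 + \sqrt{\frac{\max f - f(g)}{\max f - \min f}} \in [1, 2]$$

doubles the influence of the most set-specific genes and leaves the most
promiscuous at weight one (all weights are one when frequencies are
equal). A set's score is $S = \sum w_g |t_g| / \sum w_g$ over member genes
present on the platform; sets with no platform genes are dropped with a
warning. Significance is by permutation that respects the matched design:
the *signs* of the pair-difference vectors are flipped uniformly at
random, and the moderated t (including its variance prior) and all set
scores are recomputed each time. The p-value uses the add-one convention
$p = (1 + \#\{S^\ast \ge S\})/(1 + B)$, which keeps p-values in $(0, 1]$
and valid for any $B$; q-values are Benjamini-Hochberg across sets, with
$q < 0.1$ the conventional reporting threshold. The default $B = 500$
balances the granularity of attainable p-values against runtime at
desk-test scale.

Hypergeometric term enrichment reports the upper-tail p-value
$P(X \ge k)$ for $k$ differentially expressed genes in a term of size $m$
within a universe of $N$ genes containing $K$ DE genes, plus the sample
odds ratio $k(N-K-m+k) / ((m-k)(K-k))$, reported as infinite on a zero
cell. This unconditional odds ratio differs from conditional-MLE
estimators used by some enrichment tools; published odds ratios computed
under an unknown universe and estimator are therefore not comparable
quantities, and we make no attempt to match any.

## qRT-PCR confirmation

$-\mathrm{Ct}$ is used directly as the log2-scale abundance surrogate.
For each gene, pairs with either member missing are dropped; fewer than
three usable pairs (or zero variance) makes the gene *untestable*, which
is reported separately and excluded from the confirmation denominator. A
one-tailed paired t-test takes the microarray direction as the
alternative, so a gene can only confirm in the hypothesized direction —
a sign-reversed effect yields $p > 0.5$ by construction. No reference-gene
normalization is applied at this stage; the shared per-sample loading
effect therefore inflates variance, which is accepted (the paired design
absorbs much of it, and the classifier stage removes it exactly via
ratios). The paired (rather than unpaired) form was chosen because the
confirmation samples retain the matched structure.

## The ratio-LDA classifier

The classifier's features are log2 expression ratios: for normalizer $j$,
$r_{i} = (-\mathrm{Ct}_i) - (-\mathrm{Ct}_j) = \mathrm{Ct}_j - \mathrm{Ct}_i$.
Any additive per-sample shift (pipetting, loading, input quantity) cancels
exactly, making the feature platform-independent. `ratio_lda()` tries
every panel gene as normalizer; per candidate:

1. Cross-validation: `n_repeats = 5` repeats of `n_folds = 3` stratified
   folds. Folds are drawn at the matched-pair level — a pair never
   straddles training and held-out sets, preventing twin-leakage through
   the matching.
2. Inside each training fold only: ratios are ranked by unpaired
   two-group moderated-t p-value, discarding ratios whose mean group
   difference is below $\log_2 1.2 \approx 0.263$ cycles
   (`fc_min_ratio = 1.2`). The unpaired form is used here, unlike the
   paired discovery test, because a deployed model must score single
   future samples with no partner.
3. The top $k$ ratios feed a two-class LDA (pooled covariance, empirical
   priors); held-out samples receive the discriminant score toward the
   case class.
4. Out-of-fold scores are pooled per repeat, and sensitivity is read from
   the pooled empirical ROC at specificity cutoffs 80, 85 and 90%: the
   largest sensitivity among operating points with specificity at or
   above the cutoff (step-function convention, no interpolation — the
   conservative choice). The criterion is the mean over cutoffs and
   repeats.

$k$ ranges over `k_grid = 1..10` — with 28 training samples, larger
models cannot be estimated stably. The winning (normalizer, $k$) is
refit on all training data, and the decision threshold $\theta$ is the
smallest score cut achieving at least 85% specificity on the training
controls. Ties in the search are broken deterministically: higher
criterion, then smaller $k$, then lexicographic gene id. At prediction
time, a sample missing the Ct of any model gene is excluded and flagged
rather than imputed — mirroring how samples with multiple PCR failures
are handled in practice. An LDA fit on collinear features fails with an
error naming the offending pair; inside cross-validation such degenerate
fits score the held-out fold at zero rather than aborting the search.

Two comparators reuse the identical criterion: QDA (per-class
covariances; skipped with a warning when a class covariance is singular)
and a radial-basis SVM with library defaults (`e1071`). They are
reporting-only alternatives; the LDA model is the estimator of record.

### Pooling versus per-fold sensitivities

Reading sensitivities from pooled out-of-fold scores (rather than
averaging per-fold sensitivities) was a genuine design fork. Pooling keeps
the attainable specificity grid fine enough for cutoffs at 80/85/90% —
per-fold controls number only four or five, making "specificity
$\ge$ 0.9" nearly vacuous and inflating the null criterion well above its
analytic level. The cost of pooling is that discriminant scores from
different fold models are not perfectly commensurable, which depresses the
criterion slightly for strong models. Under pooling, the criterion on
pure-noise features sits near the analytic null level
$\mathrm{mean}(0.20, 0.15, 0.10) = 0.15$, which the test suite verifies,
together with a regression test that a deliberately leaky variant (ranking
once on all data) inflates it.

### A caution on the planted-normalizer benchmark

The synthetic panel plants one up-regulated gene V ($\beta = +1$ cycle)
and two down-regulated genes O and H ($\beta = -1$), so the ratios O/V and
H/V carry two-cycle effects. It is tempting to expect the search to
recover V nearly always, but the planted design makes normalizers
*near-equivalent*: ratios sharing a normalizer have covariance
$\Sigma = \sigma^2(I + J)$ (with $\sigma^2$ the per-gene residual variance
and $J$ the all-ones matrix), so the squared Mahalanobis separation of a
$k$-ratio model is $\sigma^{-2}\{\sum_i \delta_i^2 - (\sum_i \delta_i)^2 /
(k+1)\}$ for ratio effects $\delta$. With $\sigma^2 = 0.25$: normalizer V
with its two 2-cycle ratios gives $10.7$; any null normalizer N, whose
top ratios V/N, O/N, H/N carry one-cycle effects, gives $11.0$. Nearly
ninety candidate normalizers thus have essentially the planted one's
discriminative power, and maximizing a noisy cross-validated criterion
over them selects by winner's curse rather than by signal. Recovering the
planted normalizer *label* is therefore not a reliable property of this
benchmark, even though the selected models are (correctly) discriminative;
the test suite states the recovery property at face value and documents
its failure rather than weakening the generator. A benchmark that made the
planted normalizer uniquely optimal would need most panel genes to carry
small effects of one predominant sign, with the normalizer opposite —
closer to what a real post-discovery panel looks like.

## Evaluation

AUC is the Mann-Whitney estimator (ties count one half), verified against
exhaustive pair counting. The difference between two models scored on the
same samples is tested by stratified bootstrap: cases and controls are
resampled separately with replacement $B = 2000$ times,
$D = (\mathrm{AUC}_1 - \mathrm{AUC}_2)/\mathrm{sd}(\Delta^\ast)$, with a
two-sided normal reference; identical score vectors short-circuit to
$D = 0$, $p = 1$. The clinical comparator applies the same LDA machinery
to encoded birth-time covariates (gestational age in weeks, sex,
small-for-gestational-age status, 5-minute Apgar score, labor,
chorioamnionitis), dropping constant covariates with a warning; the
clinical model's functional form is an open choice, and using the
same classifier family keeps the comparison about the features rather
than the fitting method. Gestational-age subgroup AUCs split at the
median (strata differ by at most one sample); GA can also be added to the
feature matrix as a main effect or as interactions to check whether it
carries incremental signal. Reported percentages round half away from
zero, matching the convention by which 14/19 prints as 74% and 15/18 as
83%.

## What the generators emulate — and what they do not

`simulate_expression()` draws
$x = 2^{\mu_g + \pi_p + \beta_g \mathbb{1}(\mathrm{case}) + \varepsilon} - 1$
with probe baselines $\mu_g \sim U(5, 11)$, pair effects
$\pi_p \sim N(0, 0.5)$, Gaussian log2 noise (sd 0.5) and planted effects
with $|\mathrm{FC}|$ between 1.5 and 3. `simulate_ct_panel()` draws
$\mathrm{Ct} = \kappa_g - a_s - \beta_g \mathbb{1}(\mathrm{case}) +
\varepsilon$ with baselines $\kappa_g \sim U(20, 30)$ cycles, a shared
per-sample loading $a_s \sim N(0, 1)$ (cancelled exactly by ratios),
residual sd 0.5 cycles, completely-at-random missingness, and an optional
whole-sample failure mode (at least five missing genes in a test control)
to exercise prediction-time discard. Defaults mirror the study scale: 14
training pairs, 19 + 19 blinded test samples, 90-gene panel, and a
33-pair confirmation panel with 48 of 90 genes planted at one-cycle
effects. `simulate_genesets()` builds sets as a shared pool plus
set-specific genes, giving exact control over overlap for testing the
down-weighting.

Gaussian noise on the log2/cycle scale is standard for intensity and Ct
data but idealized: the generators have no probe-level bead noise, no
amplification-efficiency kinetics, no intensity-dependent variance, and
missingness is unrelated to abundance (real PCR failures are
abundance-biased). Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artifact of real arrays or real qPCR.

## Problem sizes and runtime choices

The test suite runs the type-I-error study at 200 replicates of 2,000
features and 14 pairs; the down-weighting study at 50 planted simulations
with 500 permutations each; the normalizer-recovery study at 50 replicates
of the full 90-gene search; bootstrap calibration at 200 replicates of 500
stratified resamples at the 19/18 test-set size. These sizes were chosen
so each Monte-Carlo standard error is small relative to the tolerance it
guards while the whole suite stays comfortably runnable on a laptop.

## Known limitations

- The permutation null for pathway scores has $2^{n_\text{pairs}}$
  attainable sign patterns; with very few pairs the add-one p-values are
  coarse.
- The normalizer search criterion is a maximum over many correlated,
  noisy cross-validation estimates; the returned criterion value is
  optimistically biased (winner's curse) and should not be read as an
  unbiased performance estimate — the blinded test set exists for that.
- The clinical comparator assumes the listed covariates; it does not
  model interactions or nonlinearity.
- GEO ingestion for full-data reproduction is out of scope; all inputs
  arrive as delimited text (expression/Ct matrices, design tables, GMT).
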