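---
title: "Screening synthetic-lethal gene pairs from paired expression, IHC and survival data"
author: "slpairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening synthetic-lethal gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slpairs)
```

# The screening problem

Two genes are synthetic lethal (SL) when losing both kills a cell while
losing either alone does not. Targeting the SL partner of a gene already
inactivated in a tumor kills tumor cells selectively, which makes SL pairs
attractive therapeutic targets — but RNAi screens that nominate them carry
many false positives. `slpairs` implements an integrated observational
screen that sifts candidate *tumor-dependent* pairs through three
independent layers of patient data:

1. **Co-differential expression.** Using per-patient log2 ratios of tumor
   versus matched normal expression, each candidate pair is scored by the
   fractions of patients in the four joint regulation patterns
   (up,up), (up,down), (down,up), (down,down) at a fold cutoff, with a
   label-exchange permutation null and Storey q-value FDR control.
2. **Marker-pair synergy with clinical phenotypes.** Immunohistochemistry
   (IHC) markers are dichotomized by per-marker abnormality criteria and all
   distinct-protein marker pairs are tested (Fisher's exact test) against
   five dichotomized clinical features. A pair is *synergistic* when the
   joint-abnormal state associates with a feature while neither single
   marker does, and *putative synergistic* when the pair's p-value is
   significant and strictly smaller than both singles'. Candidates are
   expanded transitively by the 2-hop rule (A–B and B–C known ⇒ propose
   A–C).
3. **Survival.** Kaplan–Meier curves, Mantel–Haenszel log-rank tests,
   univariate and stepwise-AIC multivariate Cox models (with VIF
   collinearity screening) establish prognostic markers, and transferred
   proportional-hazards risk models — scored by the hazard ratio of the risk
   score and the Gönen–Heller concordance probability estimate (CPE) —
   establish predictive ones.

Every stage is exercised on synthetic cohorts produced by the package's own
generator, so the full pipeline is testable without any external download.

# The expression pattern screen

For genes $g_1, g_2$ and patient $i$ with log2 ratios $x_{i1}, x_{i2}$, the
patient is *up* for a gene when $x \ge \log_2 c$ and *down* when
$x \le -\log_2 c$, with fold cutoff $c = 1.5$ by default. The half-open
neither zone $[1/c, c)$ contributes to no pattern, so the four fractions
need not sum to one. All ratios are stored in log base 2; "1.5-fold" always
means $|\log_2 \text{ratio}| \ge \log_2 1.5$.

**Permutation null.** Exchanging a patient's tumor and normal labels negates
that patient's log ratios for *both* genes jointly — the only exchange
consistent with relabeling tissues rather than individual measurements. Each
of `nPerm` permutations flips every patient independently with probability
1/2; the p-value uses the add-one convention $(1 + \#\{\text{permuted} \ge
\text{observed}\})/(1 + N)$, so $p > 0$ always and, at $N = 10{,}000$, a
maximal observed statistic reports $1/10001$, which prints as $0.0001$ at
four decimals (the raw $c/N$ estimate is available by flag). When
$2^{n} \le N$ the full set of $2^n$ sign assignments is enumerated instead
and the p-value is the exact tail fraction. Patients missing either gene are
dropped pairwise.

Because the pattern count is integer-valued, permutation ties make the test
slightly conservative: its measured type-I error at $\alpha = 0.05$ sits
near 0.03–0.04 rather than 0.05. This is a property of any exact
randomization test with a discrete statistic, and the test suite checks
calibration with exact binomial bounds rather than against a continuous
uniform.

**FDR.** q-values follow the Storey recipe: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, \dots, 0.95$, smoothed by a cubic smoothing spline
(df = 3) and read off at $\lambda = 0.95$, clipped to $(0, 1]$; the step-up
minimum $\hat\pi_0 \, m \, p_{(j)} / j$ gives the q-values. `method = "bh"`
fixes $\pi_0 = 1$, reproducing Benjamini–Hochberg exactly. The default
family is all tested (pair, pattern) hypotheses; the synergy stage uses one
family per clinical feature, configurable to a global family.

**Ranking.** Pairs with any pattern fraction above 1% are kept and sorted in
decreasing lexicographic order of the (up,up), (up,down), (down,up),
(down,down) fractions — knockdown being easier than overexpression, jointly
up-regulated pairs rank first — with remaining ties broken by gene symbol.

# The IHC synergy screen

The bundled 23-marker panel (`defaultMarkerPanel()`) stains 20 proteins,
three of them at two cellular locations. Grades live on the ordinal scale
$0 < \pm < 1+ < 2+ < 3+$; each marker's abnormality criterion is a
directional threshold on that scale (or on percent staining, e.g. membrane
CDH1 at $\ge 70\%$), boundary-inclusive for $\ge$. Pairing all markers with
distinct proteins yields $\binom{23}{2} - 3 = 250$ testable pairs.

The five clinical dichotomies are: death before 3 years versus survival past
3 years (patients censored alive before 36 months are excluded from this 2×2
by default — counting them as non-adverse is offered as a flag, since
including them would bias the margin); poorly versus well/moderately
differentiated grade; metastasis yes/no; nodal N1–N2 versus N0; and stage
III–IV versus I–II.

Fisher's exact test uses the probability-ordering two-sided convention (sum
of hypergeometric probabilities of tables at most as probable as the one
observed, with a ~1e-7 relative tie tolerance); mid-p and doubling
conventions differ in the third decimal and are deliberately not used. A 2×2
with an empty margin returns $p = 1$: no association is testable.

The *putative* label requires the pair p-value itself to be below
$\alpha$ and strictly smaller than both single p-values. On printed,
rounded record tables a pair p can tie a single p at the displayed
precision; the strict rule then classifies such a row "none", which is a
rounding artifact of the display, not of the method.

One caveat the synthetic experiments make explicit: an *interaction-only*
effect (odds raised solely in the joint-abnormal state) still induces a
marginal single-marker association, because joint-abnormal patients are a
subset of each single margin. With a strong planted effect the screen
therefore most often labels the pair *putative* rather than fully
*synergistic*; what the generator guarantees — and what the tests assert —
is that the single-marker association vanishes conditional on the partner
being normal, and that the planted pair enters the predicted list.

# Survival analysis choices

Kaplan–Meier estimation, the log-rank test and Cox regression are delegated
to the `survival` package; ties use the Efron approximation (the default of
`coxph`, and the appropriate choice for month-resolution data). Stepwise
selection is bidirectional from the full candidate model, taking whichever
single add/drop most reduces AIC until no move does; the null model's AIC is
$-2$ times the null partial log-likelihood. VIFs are computed directly as
$1/(1-R^2_j)$ from least-squares regressions with intercept; perfectly
collinear columns report `Inf` rather than a large number.

Expression-based marker rules ("2-fold over-expression of RAD54B",
pair rules like FEN1↑–RAD54B↑) flag a subject only when *every* gene passes
its directional cutoff; ↓ means a fold of at most $1/c$. Cutoffs are
boundary-inclusive, matching the $\ge$ convention of the IHC criteria, and
per-gene overrides are supported (e.g. a laxer 1.2-fold cutoff for one gene
in a cohort where the default flags nobody). For cohorts without matched
normals the reference defaults to the per-gene cohort median — a
pragmatic, explicitly configurable choice, since no reference is canonical
there.

# Predictive risk models

`fitRiskModel()` fits a multivariate Cox model on marker indicators, with or
without age/stage covariates, and records its design so `predictRisk()` can
transfer the linear predictor $\sum \beta x$ to any cohort providing the
same variables. Evaluation reports the hazard ratio of the *continuous*
score (per unit of linear predictor; no per-SD scaling is applied), and the
Gönen–Heller CPE

$$K = \frac{2}{n(n-1)} \sum_{i<j} \left[
  \frac{\mathbf 1(s_i \ge s_j)}{1+e^{s_j-s_i}} +
  \frac{\mathbf 1(s_j > s_i)}{1+e^{s_i-s_j}} \right],$$

the model-based concordance of proportional-hazards scores — unaffected by
censoring by construction, equal to 0.5 for constant scores, shift-invariant
and monotone in score separation. Harrell's C is intentionally *not*
substituted; the two estimands differ under censoring. Kaplan–Meier display
groups come from a median split of the validation scores with ties assigned
to the low-risk group. A marker constant in a validation cohort (e.g. no
subject jointly positive) makes the evaluation not-applicable rather than
an error.

# The synthetic-cohort generator

`cohortSpec()` fixes the study design; `generateStudy()` renders it
deterministically. Defaults mirror the study design the screen was built for:
83 patients for the paired-expression cohort (pass `nPatients = 131` for
the IHC cohort), baseline log2-ratio noise SD 1.0, marker marginal
abnormality rates equal to the default panel's observed rates, and a
clinical mix of a stage-heterogeneous adenocarcinoma cohort (baseline
adverse rates: 3-year death 0.45, poor grade 0.35, metastasis 0.20, N1–N2
0.45, stage III–IV 0.40; 10% of patients censored alive before 36 months).
Survival times are exponential with hazard
$h_0 e^{\sum\beta x}$ ($h_0 = 0.02$/month, i.e. median ~35 months at
baseline) under independent uniform censoring on $[0, 120]$ months — the
simplest censoring-complete model consistent with proportional hazards.

Planted structure is explicit and minimal: a co-expression pattern is
planted by giving a Bernoulli(penetrance) subset of patients exactly
$\pm\log_2(\text{fold})$ on both genes; marker-pair/feature synergy is
planted by multiplying the adverse odds *only* in jointly abnormal patients;
abnormal markers are mapped back to an ordinal grade drawn uniformly from
the grades satisfying the marker's criterion (the complement for normal).
One global seed is split into fixed, labelled component streams, so adding
markers never perturbs the expression draws. Expression and IHC are
generated independently — the screen treats them as separate evidence
layers, and no joint model between mRNA and protein abnormality is assumed.

What the generator does *not* emulate: probe-level microarray artifacts and
normalization, correlated gene backgrounds, RNA-seq count noise,
non-proportional or time-varying hazards, and informative censoring. Tests
passing on these cohorts demonstrate that the machinery is correct and
calibrated under its stated model, not that real cohorts satisfy that model.

# Problem sizes and numerical conventions

The test-suite and acceptance-script simulations use cohorts of 83–131
patients (matching the two study cohort sizes), 199-permutation nulls over
500 replicate cohorts for calibration checks, 100–200 seeds at $n = 1000$
for hazard-ratio recovery, and 40 seeds at $n = 500$ for stepwise-selection
behavior — sizes chosen so each check has clear statistical resolution.
Exhaustive enumerations back the Monte-Carlo paths wherever feasible: all
$2^n$ sign flips for $n \le 13$, the full hypergeometric support for
Fisher's test, and a brute-force double loop for the CPE.

Degenerate inputs are handled explicitly: all-zero matrices give $p = 1$;
features with no variation warn and record $p = 1$ across their family;
all-censored datasets are rejected by the hazard models; constant risk
scores mark an evaluation not-applicable.

# Limitations

- The screen is observational: synergy labels are association statements,
  not causal SL calls; the 2-hop expansion in particular is a hypothesis
  generator.
- Exact conditional tests are conservative at these cohort sizes; family
  q-values inherit that conservatism.
- Interaction-only planting cannot produce marginally null singles (see
  above); claims about "synergistic" versus "putative" frequencies depend
  on marker prevalence and effect size.
- The exponential/uniform-censoring survival generator checks estimator
  correctness, not robustness to misspecified hazards.
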