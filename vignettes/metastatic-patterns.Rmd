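---
title: "Modelling metastatic progression patterns with metspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metastatic progression patterns with metspread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(metspread)
```

## The analysis problem

Autopsy remains the definitive way to measure total metastatic burden: a
complete post-mortem examination records every secondary site a tumor
colonized, free of the sensitivity limits of clinical imaging. Given a
registry of autopsied patients, `metspread` asks four questions:

1. Which primary tumors metastasize where, and how strongly does a route
   deviate from what the cohort-wide site frequencies would predict?
2. Do histology, smoking etiology, nodal status or sex shift these
   patterns?
3. How well does the set of secondary sites predict the primary — the
   cancer-of-unknown-primary (CUP) scenario run backwards?
4. How do primary and secondary sites relate to *total lifetime* (age at
   death), with cancer-related deaths as events?

The registry data model has one row per autopsied patient: demographics,
cancer status, a primary site from a fixed 16-category vocabulary, a
20-bit secondary-site indicator vector, histology, regional nodal status
and death information. Regional lymph-node involvement is deliberately
*not* a secondary site: only non-regional nodes (`LYM`) count as
metastasis, and regional disease is carried by `nodal_status` alone, so
the two notions can be related (N+ vs N− contrasts) without circularity.

## The inclusion cascade

`apply_inclusion_filters()` reduces a raw registry to the analysis cohort
in a fixed order: no cancer, then cancer without metastasis, then rare or
multiple primaries. A record matching several reasons is counted once,
under the first matching reason. The order itself is a design choice —
any record without cancer trivially has no metastases, so precedence is
needed to make the audit trail deterministic; we chose the order in which
the criteria are stated, which also matches how a pathologist would
triage records. The conservation identity (exclusion counts plus included
patients equal the input size) is enforced by construction and tested as
a property.

## Fractions, relative risks, and the two-sided Fisher choice

The *fractional method* reports conditional proportions: progression
fractions (share of tumors of primary $p$ reaching site $s$), origin
fractions (share of metastases at $s$ coming from $p$; defined rows sum
to 1), and site–site co-occurrence as the Jaccard index
$|A \cap B| / |A \cup B|$ over patient sets.

The *relative-risk method* measures enrichment against the whole cohort:

$$RR(a,b) = \frac{f(a \wedge b)}{f(a)\,f(b)},$$

with all frequencies taken over the full included cohort. $RR > 1$ means
the pair co-occurs more often than the marginal frequencies predict.
Cells with a zero-frequency margin are undefined, carried as `NA`, and
excluded from multiple-testing families.

Significance is assessed with Fisher's exact test on the per-cell 2×2
patient table. We use the *two-sided* test in its conventional
minimum-likelihood form (summing all tables no more probable than the
observed one) because the screen flags both enrichment and depletion;
a one-sided test would have to be run twice and recombined. The test
suite checks the p-values against a from-scratch hypergeometric
enumeration rather than trusting any library definition.

FDR control uses Benjamini–Hochberg at 5%, applied **per matrix**: the
16×20 primary→secondary screen is one family, the 190 unordered
secondary-site pairs another, and each subgroup comparison's 20 sites a
third kind. Families never mix statistics of different types; the family
membership is recorded in the JSON summary written next to each exported
matrix. Whether screened heatmaps should use raw p or adjusted q is
genuinely ambiguous in practice; we expose both matrices and flag on q.

For the per-site heterogeneity test accompanying the hit-frequency
summary we use a chi-square goodness-of-fit of the 20 per-site hit counts
against equal proportions. The site indicators are correlated within
patients, so this is a descriptive screen, not an exact test; we chose it
over Cochran's Q for transparency and note the caveat here rather than
hiding it in output.

## Subgroup contrasts

`compare_groups()` stratifies by histology (adenocarcinoma vs squamous),
smoking etiology, nodal status or sex, optionally within one primary
(e.g. lung-only histology contrasts). Smoking-relatedness is a fixed
property of the primary site — the seven sites whose smoking population
attributable fraction reaches 20% (lung, head and neck, esophagus and
stomach, kidney, pancreas, urinary tract, cervix). Records with unknown
histology or nodal status are dropped *per comparison*, not globally, and
the drop count is reported: discarding them globally would shrink every
other analysis for no reason. Fisher's exact test is used for the
two-group contrasts for consistency with the RR screen and exactness at
the small counts that rare sites produce.

## Primary-site prediction

Two models address the CUP question. First, separately per primary, a
multivariate logistic regression of (primary = target) on all 20 site
indicators yields odds-ratio profiles with 95% Wald intervals and BH
correction across the 20 covariates. Rare sites (thyroid, bone marrow,
spleen are each under ~5%) readily separate small strata, so the fit adds
a weak ridge penalty — $\tfrac{1}{2}\lambda\sum_j \beta_j^2$ with fixed
$\lambda = 1$, intercept unpenalized, solved by Newton/IRLS with the Wald
covariance taken from the penalized information matrix. At cohort scale
(hundreds of patients) the penalty's bias is negligible (the
parameter-recovery suite verifies nominal CI coverage), while divergence
under separation is impossible; covariates whose marginal 2×2 table
against the outcome has an empty cell are additionally flagged as
separation-prone. We wrote this solver by hand because penalized fits
with analytic Wald covariances are not what off-the-shelf penalized-GLM
tools return.

Second, a multinomial logistic model over all 16 primaries is validated
by repeated random subsampling: training sets of $\lfloor 2n/3 \rfloor$
patients drawn without replacement (not stratified — splits are plain
random draws), the remaining third scored by top-$k$ accuracy,
$k = 1, 2, 3$. Summaries are the mean and the 2.5th/97.5th percentiles
across splits. Ties in predicted probability are broken by fixed
vocabulary order — determinism over optimism. Per-primary top-3 recall is
computed by pooling test-set outcomes over all splits (pooling, rather
than averaging per-split recalls, keeps rare primaries estimable); the
output labels it as pooled. A training set can lack a rare class; the
affected split is retained, its test rows scored against the fitted
classes (necessarily missing that class), and the event is counted and
reported. The `OTH` indicator is included among the covariates by
default — it carries signal (some primaries shed unusual metastases) —
and can be excluded by subsetting the registry columns if a stricter
vocabulary is wanted.

## Total-lifetime Cox model

`fit_lifetime()` fits a Cox proportional-hazards model with **age at
death** as the time axis. This is population-descriptive, not
prognostic: it describes the lifetime burden associated with tumors and
metastases at given sites, not post-diagnosis survival. Cancer-related
deaths are events; other deaths remain in the risk sets as censored.
Covariates are sex, the primary site one-hot with lung (the most common
primary) as reference, and the 20 site indicators. Ties use the Breslow
approximation by default — the convention of the desktop statistics
packages this analysis style originated in — with Efron available by
flag. Constant covariates are dropped with a message rather than
returning `NA` rows. Left truncation (patients enter observation at
birth only in the actuarial sense) is *not* modelled; with age-at-death
data there is no natural entry time, and this is a documented limitation
of the total-lifetime design rather than of the implementation.

## The synthetic-registry generator

Registries of this kind are not shareable, so the generator is
first-class, tested code, not a throwaway fixture. It emulates:

* the stratum structure (no cancer / cancer without metastasis / rare or
  multiple primaries / eligible), by default at the worked-example
  proportions 4497 : 1016 : 76 : 1008 of 6597;
* a 16-category primary mixture (default: lung most common at ~28% of the
  eligible stratum; smoking-related primaries jointly ~59%);
* per-primary secondary-site marginals (16×20), defaulting to
  cohort-level site rates scaled per primary so mean burden spans roughly
  2.3 to 5.9 involved sites, with overrides for canonical routes
  (prostate→bone ~0.9, breast→liver/bone ~0.8, melanoma→spleen/skin/
  meninges elevated, lung→adrenal/brain elevated);
* co-occurrence, via a latent-Gaussian threshold (Gaussian-copula) model:
  each eligible patient draws a 20-dimensional standard normal with
  correlation matrix `coupling`, and site $j$ fires iff
  $z_j < \Phi^{-1}(p_{pj})$. Correlations are specified on the *latent*
  scale, not the RR scale; the property suite verifies that raising a
  coupling entry raises the realized co-occurrence RR of that pair.
  Independent Bernoulli draws could not express the co-occurrence
  analyses' premise at all. Default coupling is exchangeable at 0.15, a
  mild positive dependence consistent with burden heterogeneity across
  patients. Supplied couplings that are mildly indefinite are repaired by
  eigenvalue clipping (with a message) and rescaled to unit diagonal;
  matrices with eigenvalues below −0.25 are rejected as misspecified.
* lifetimes, from a Weibull baseline (shape 6, scale 80 years — a
  realistic human age-at-death distribution) under proportional hazards
  with sex, primary and per-site log-hazards; the event indicator is an
  independent Bernoulli (`cancer_death_prob`, default 0.85).

Eligible patients must be metastatic, so all-zero site draws are redrawn
(bounded at 100 attempts, then one site is assigned proportional to the
marginals, with a message). This conditioning inflates marginals by at
most the all-zero probability — negligible at realistic marginals, and
accounted for explicitly in the recovery tests.

What the generator does **not** emulate: histology and nodal status are
drawn independently of the metastasis vector given the primary, so
histology/nodal subgroup contrasts on synthetic data are null
(machinery-testing only); there is no within-patient temporal ordering of
metastases; no treatment effects; and the default marginal matrix is
illustrative where the literature prints no value. Passing tests on
synthetic data therefore demonstrate the *pipeline's* correctness —
estimator identities, calibration, recovery of known parameters — not any
biological claim about real registries.

## Numerical and design details

* **Determinism.** Every stochastic routine takes an integer seed and
  restores the caller's RNG state; identical config + seed gives
  byte-identical registry files, CV reports and graph exports. The
  worked-example fixture (`make_paper_fixture()`) additionally allocates
  stratum and primary counts by largest-remainder rounding so the counts
  are exact, not merely expected.
* **Clustering.** Fraction matrices: Manhattan distance on raw values.
  RR/OR matrices: Euclidean on log2 values; non-positive or undefined
  cells are masked pairwise, with each distance computed over mutually
  defined coordinates and rescaled by coverage. Average linkage
  throughout. Dendrogram leaf order is canonicalized — at every merge the
  subtree containing the lexicographically smallest leaf comes first — so
  the order is invariant to input row permutation (resolving the
  mirror-image ambiguity of hierarchical clustering). Both row and column
  clusterings are emitted, since either margin of a heatmap may be of
  interest.
* **Graphs.** The progression network has one node per primary (size =
  patient count) and per secondary site (size = hit count), one edge per
  defined positive progression fraction, colored by the RR screen's
  enriched/depleted flags. Export is GraphML (typed attributes,
  round-trips exactly) with an optional JSON sidecar; no figure rendering
  is attempted.
* **Degenerate inputs.** Header-only registries parse to empty; empty
  cohorts error early with a clear message; single-class training sets
  yield a degenerate classifier; primaries with no patients produce `NA`
  matrix rows and are dropped from rank tests with a warning.

## Problem sizes

The test suite exercises exhaustive oracle equivalence (relative risk and
Fisher p) on cohorts of up to 30–40 patients, null calibration of the RR
screen on a 50 000-patient independence simulation, logistic and Cox
parameter recovery on 100 seeded replicates each (n = 600 and 400), and
multinomial validation at n = 5000 with 50 splits. The acceptance script
runs the full 1000-split cross-validation protocol on the 1008-patient
worked example. These sizes were chosen to make Monte-Carlo error small
relative to the tolerances being checked.

## Known limitations

* Printed reference values from the motivating analyses of real autopsy
  registries are documented anchors, not reproducible targets: the
  underlying patient data are unreleased, so tests assert them only on
  synthetic data where the generator encodes them.
* The RR statistic is symmetric in its arguments and agnostic to
  direction; causal routing (which site seeded which) is outside the data
  model.
* The heterogeneity chi-square ignores within-patient correlation (see
  above).
* The lifetime model measures association with age at death, not
  post-diagnosis prognosis, and does not model left truncation or
  competing risks.
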