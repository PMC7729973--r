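---
title: "Methods: quarter-resolved udder microbiota analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quarter-resolved udder microbiota analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`quartermilk` analyses quarter-level bovine milk microbiota from sequence-
variant (SV) count tables. This vignette is the package's account of its
methods: the models and rules it implements, the parameters that matter,
what the synthetic data generator does and does not emulate, and the
numerical and design choices behind the implementation.

## The dysbiotic-quarter rule

The udder's four quarters are anatomically separate, so each cow at each
sampling provides its own internal reference population. A quarter is
called dysbiotic for family $F$ when

$$\text{share}(F, q) > 0.60 \quad\text{and}\quad
  \text{share}(F, q') < 0.20 \;\; \forall\, q' \neq q,$$

with both thresholds strict, evaluated only for cows where 3 or 4 quarter
samples are available at that sampling. Design choices:

* **Per-family evaluation.** The rule is applied to every family
  independently; two quarters both above 60% for the same family block each
  other (the second quarter is necessarily ≥ 20% from the first quarter's
  viewpoint), but different families may each yield a call in the same
  cow-period.
* **Raw proportions.** Shares are computed from raw filtered counts —
  the rule is defined on percent of reads. Normalized abundances are never
  used for calling.
* **"Not evaluated" is a distinct state.** Cow-periods with fewer than 3
  quarters return a sentinel rather than "no call", so the evaluation
  denominator (the count of evaluable cow-periods) is always computable.
* **Boundary behaviour.** A dominant share of exactly 0.60 or a sibling
  share of exactly 0.20 never produces a call; proportion vectors must sum
  to 1 within $10^{-8}$ or the caller raises a validation error.

A single-quarter definition cannot detect dysbiosis affecting more than one
quarter simultaneously; that is a stated limitation, not an oversight.

## Quality filtering

Four rules in a fixed, load-bearing order: (1) SVs shorter than 375 bases
are removed (strict; a 375-base SV is retained); (2) specimen samples with
fewer than 2000 reads are removed — controls are exempt, being expectedly
shallow; (3) SVs with fewer than 10 reads, summed over surviving specimen
samples, are removed; (4) control-based contaminant removal. The sample
filter precedes the SV filter deliberately: an SV whose support drops below
10 reads once a shallow sample is gone is removed, so swapping the order
changes the result (the test suite pins this with a fixture on which the two
orders genuinely differ). The chain re-applied to its own output is the
identity on the test fixtures; in general a removed SV can push a marginal
sample below the depth threshold on re-application, which is why the order
is documented as part of the method.

Control rules:

* **(a) positive control / mock.** Any SV detected in a positive control
  whose genus is not on the mock-community list (default: the 20-strain
  even-mix standard) is removed. Matching is at genus level because mock
  references are strain lists while SV taxonomy is reliable to genus.
* **(b) negative controls.** Any SV present in at least half the negative
  controls whose mean relative abundance there exceeds its mean relative
  abundance in specimens is removed. This is a deliberately transparent
  prevalence-plus-enrichment rule — a stand-in for black-box contaminant
  scoring, with both thresholds (`neg_prevalence = 0.5`,
  `neg_enrichment = 1.0`) exposed in the API.

## Normalization and diversity

**CSS (cumulative sum scaling).** For sample $j$, the scaling factor
$s_j$ is the sum of counts up to the median of the sample's nonzero counts;
normalized values are $c/s_j \times 1000$. The quantile is fixed at 0.5
(exposed as a parameter); the adaptive quantile-selection of the reference
approach is intentionally not reproduced. Alpha diversity is computed on raw
filtered counts, not CSS values: richness estimators depend on integer
singleton/doubleton counts that scaling destroys.

**Chao1** uses the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, finite when no doubletons are observed.
**Shannon** uses natural logarithms. **Bray–Curtis** is
$\sum|x-y|/\sum(x+y)$ on CSS-normalized abundances; **Jaccard** is computed
on presence/absence, as a membership-based complement to Bray–Curtis. The
Bray–Curtis triangle inequality is not asserted anywhere — it is not a
metric.

**Ordination.** PCoA (eigendecomposition of the Gower double-centred
matrix; axes with non-positive eigenvalues dropped) is the ordination used
throughout, including as input to Procrustes. NMDS is deliberately not
implemented: it adds an iterative optimizer with convergence pathologies,
and the question Procrustes answers — do the two dissimilarity views group
samples the same way — is equally well posed on PCoA. Pipeline-level
Procrustes compares the 10 leading axes; the statistic `m2` is the
symmetric normalized residual $1 - (\sum \sigma_i)^2$ after centring and
unit-trace scaling of both configurations, so it is invariant to swapping
the inputs.

**Permutation tests.** One-factor PERMANOVA partitions squared
dissimilarities; dispersion homogeneity embeds samples by PCoA and runs a
one-way F on distances to group centroids, permuting group membership.
P-values use the add-one estimator $(1+b)/(1+B)$ — except when the number
of distinct group relabelings is at most the requested permutation count,
in which case all labelings are enumerated and the p-value is exact.
F comparisons in the permutation tail use a relative tolerance of $10^{-8}$
so exchangeable inputs (all permuted statistics equal) give $p = 1$ rather
than an artefact of floating-point rounding. The Wilcoxon rank-sum
comparison of alpha diversity enumerates all rank splits when the combined
sample size is at most 12 (midranks for ties) and otherwise delegates to the
tie-corrected normal approximation. Groups of size 1 get dispersion 0 but
are excluded from the dispersion F test with a warning; ties in "most
abundant families" for the correlation analysis break lexicographically.

## The synthetic generator

`generate_dataset()` emulates the structure of a two-farm cross-sectional
quarter-milk study so the pipeline can be exercised with known truth:

* **Herd structure:** 30 cows per farm (farms A and K), four quarters, two
  sampling periods; each quarter sample is missing with probability 0.06,
  which exercises the caller's 3-or-4-quarters eligibility rule.
* **Composition:** family proportions follow a logistic-normal model:
  farm-specific baseline means (per-farm columns of
  `default_family_baseline()`, dominated by Corynebacteriaceae ~38%/31% and
  Staphylococcaceae ~13%/19%), a cow random effect (SD 0.45, log scale), an
  independent quarter effect (SD 0.35) and a latent antagonism between the
  two core families (log-scale covariance −0.25). A logistic-normal was
  chosen over a Dirichlet precisely so this negative coupling could be
  imposed directly. The farm-K baseline for Pseudonocardiaceae is set to
  0.1% (a strictly positive stand-in for a reported zero, since
  logistic-normal means must be positive).
* **Mean calibration.** The baselines are target *means*, but the mean of a
  logistic-normal is not the softmax of its location — noise deflates
  dominant components. The generator therefore runs a short Monte-Carlo
  fixed-point correction of the location vector (3000 draws, 6 iterations)
  before sampling, so realized mean abundances track the configured
  baselines; residual deviations (a point or two) come from the injected
  dysbiosis events.
* **Counts:** family mass splits across 8 SVs per family by a Dirichlet
  draw fixed per dataset; counts are multinomial at log-normal depth
  (median ≈ 5,988, mean ≈ 12,549 reads; `depth_log_sd` is pinned by that
  mean/median ratio). Depth is independent of composition by default
  (`dysbiosis_depth_factor = 1`): library normalization during sequencing
  largely decouples read depth from bacterial load, so elevated load in
  dysbiotic quarters is expressed in the colony counts, not the read depth.
* **Dysbiosis events** are injected post-hoc with probability 36/106 per
  evaluable cow-period: one quarter's chosen family is set to a dominant
  fraction drawn from 0.65–0.95 and its share in sibling quarters is capped
  at 0.15, with the quarter renormalized — so truth events satisfy the
  caller's rule by construction and with margin. The injected family is
  drawn with weights 20:5:4:7 (Staphylococcaceae : Streptococcaceae :
  Enterococcaceae : the remaining non-core families). Because multinomial
  noise at low depth could still push a realized share across a threshold,
  constrained samples are redrawn (up to 50 times) until the event holds on
  the counts — the truth log is a guarantee, not a probabilistic statement.
* **Controls and contaminants:** negative controls contain only the
  designated contaminant SVs (three Proteobacteria families typical of
  reagent background) at ~300-read depth; the same SVs appear at trace
  levels in specimens, so they survive the support filter and are removed
  by control rule (b), as logged in the truth record. Positive controls are
  a near-even 20-strain mock plus a 3% spill-in of designated non-mock SVs
  removed by rule (a). No quantitative description of real negative-control
  composition was available; the contaminant profile is a documented free
  choice.
* **Culture:** every dysbiotic quarter is culture-infected; other quarters
  are infected with probability 0.36, landing the overall infected fraction
  near 42%. Dysbiotic samples always yield isolates of the injected family
  when it has cultivable species in the built-in family→species dictionary
  (the strictly anaerobic Clostridiales families do not — mirroring the
  reality that such organisms are rarely recovered on standard media);
  identification scores are drawn from (2.0, 2.6].

**What passing tests do and do not show.** The generator reproduces the
marginal family abundances, depth distribution, herd structure, event
frequencies and truth-consistent culture results — so tests against it
demonstrate the pipeline's correctness and calibration, not biological
discovery. It does not emulate: SV-level ecological turnover within
families, phylogenetic structure, chimeras or sequencing error (the
pipeline starts at the SV table), depth–composition coupling, multi-quarter
dysbiosis, or the strong presence/absence structure of real data — which is
why the Bray–Curtis and Jaccard ordinations of synthetic data correspond
significantly under PROTEST but with a high `m2`. Because infection is
coupled to dysbiosis by design, the composition-vs-infection PERMANOVA
typically rejects on synthetic data; on the real system that association
was weak. And because default sample depths fall below 2000 reads about
18% of the time, a corresponding share of injected events is legitimately
lost to the depth filter; recovery statistics are therefore reported
against the *recoverable* events (surviving QC in a still-evaluable
cow-period), for which recall is 100% by construction.

## Problem sizes

The test suite runs small instances (8-cow herds for module tests;
exhaustive-enumeration checks at $n \le 8$; 500 null replicates of 20
samples at 199 permutations for type-I calibration; 50 replicate datasets
for generator calibration; one full 60-cow end-to-end run at 999
permutations) — sizes chosen so the whole suite completes in about a
minute while keeping every statistical check at meaningful resolution.

## Open questions resolved

* **"% positive cows":** whether a cow counts as positive for a family on
  detection in *any* sample or in *every sampled period* is ambiguous;
  `family_profiles()` reports both (`pct_cows_any`,
  `pct_cows_all_periods`).
* **Missing colony data** yields infection status `unknown`, excluded from
  infected/not-infected groupings rather than imputed.
* **Interacting removals:** control-based and taxonomy-based SV removals
  are logged as separate rules; no attempt is made to reproduce any
  specific combined removal count.
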