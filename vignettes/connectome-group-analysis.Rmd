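---
title: "Weighted connectome metrics, permutation ANCOVA and brain-behaviour correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted connectome metrics, permutation ANCOVA and brain-behaviour correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucnet)
library(dplyr)
```

## The analysis this package implements

Structural brain networks ("connectomes") built from diffusion-weighted
tractography represent each of 90 anatomically defined regions (78
cortical, 12 subcortical) as a node and the estimated white-matter
connection between each pair of regions as an edge weighted by its
streamline count.  `strucnet` starts from those subject-level weighted
matrices — everything upstream (tractography, parcellation, streamline
counting) is out of scope — and implements the downstream statistics
for a three-group case-control design: healthy older adults (HOA) and
depressed patients with mild cognitive impairment, split by cerebral
amyloid status into amyloid-positive (LLD-MCI-A+) and amyloid-negative
(LLD-MCI-A−) groups.

The pipeline has four stages:

1. **Network measures** (`compute_all_metrics()`): per subject, four
   nodal measures — degree $k_i$, strength
   $s_i = \sum_j w_{ij}$, Onnela weighted clustering
   $C_i = \frac{1}{k_i(k_i-1)}\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$,
   and regional efficiency
   $E_i = \frac{1}{N-1}\sum_{j \ne i} 1/d_{ij}$ — and five global
   measures: edge density, total strength, the mean clustering
   coefficient $C$, the characteristic path length $L$ (mean
   shortest-path distance over reachable pairs), and small-worldness
   defined as the literal ratio $S = C/L$.
2. **Group comparison** (`run_nodal_group_analysis()`): a
   permutation-based ANCOVA of every measure on group, controlling for
   age, sex and education, with Benjamini–Hochberg FDR across the 90
   nodes per nodal measure, post-hoc pairwise permutation ANCOVAs with
   their own FDR across the three contrasts, and covariate-adjusted
   group means with confidence intervals
   (`adjusted_group_means()`).
3. **Brain–behaviour association** (`run_correlation_analysis()`):
   partial Pearson correlations between network measures and cognitive
   test scores within each patient group, controlling for the same
   covariates, with FDR across nodes.
4. **Cohort statistics** (`reproduce_table1()` and friends): the
   classical one-way ANOVA F, pooled t and Pearson χ² statistics of the
   demographic table, recomputable exactly from the published group
   means and standard deviations through moment-matched samples.

A synthetic-cohort generator (`simulate_study()`) produces studies with
this exact structure — including the covariate confounding and planted
effects — so every stage is testable without access to subject-level
imaging data.

## Design choices in the network measures

**Edge lengths.** Shortest paths need a connectivity-to-length mapping;
`strucnet` uses the standard reciprocal $l_{ij} = 1/w_{ij}$, so strong
(high-streamline-count) connections are short.  Distances are computed
by Dijkstra's algorithm via igraph; the test suite verifies them
against a naive Floyd–Warshall implementation on hundreds of small
graphs.

**Clustering variant and weight normalization.** The weighted
clustering coefficient is Onnela's geometric-mean form, the common
weighted-toolbox default.  Dividing all weights by their maximum first
(`normalize_weights = TRUE`) bounds $C_i$ in $[0,1]$; the package
default is **off**, because the study this design follows reports
nodal clustering values on the order of tens (e.g. $28 \pm 4$), which
is only possible on unnormalized streamline-count weights.

**Regional efficiency.** Descriptions of this measure sometimes read
as "the average of the shortest path lengths from the node to all
others", which is an average *distance*, not an efficiency.  `strucnet`
implements the standard inverse-distance definition (the toolbox
convention), under which a complete unit-weight network has
$E_i = 1$ everywhere.

**Unreachable pairs.** Tractography networks are near-fully connected;
when a pair is nonetheless unreachable, the CPL excludes those pairs
with a warning rather than failing or substituting a finite penalty,
and efficiency uses $1/\infty = 0$.  A network with no finite pair at
all is an error.

**Small-worldness.** $S = C/L$ is taken literally; the conventional
random-network-normalized $\sigma$ is deliberately not computed.

**Validation.** Matrices must be symmetric, nonnegative,
zero-diagonal.  Nothing is repaired silently: asymmetry beyond a
relative $10^{-8}$ is an error; within that tolerance the upper
triangle is mirrored with a message.

## The permutation ANCOVA

The group test is a partial F comparing the full linear model
(intercept + group indicators + covariates) with the reduced model
(intercept + covariates):

$$F = \frac{(RSS_{red} - RSS_{full})/(g-1)}{RSS_{full}/(n-g-q)}.$$

Its reference distribution is obtained by permutation.  Because the
covariates differ between groups (the patient groups are ~8 years
older and ~7 years less educated than the controls), a naive shuffle
of group labels is miscalibrated; the default scheme is therefore
**Freedman–Lane**: regress the outcome on the covariates alone,
permute the residual vector, add the covariate fit back, and recompute
the partial F on each reconstructed outcome.  A label-shuffle mode is
retained for comparison.  The p-value is $(b+1)/(m+1)$ so it can never
be zero, with $m = 10{,}000$ permutations by default (tests and
examples use reduced counts).  For tiny two-group problems an
exhaustive mode enumerates all assignments and returns the exact
permutation p-value; mathematically tied F values (an assignment and
its complement) are counted as ties with a relative $10^{-12}$
tolerance.

Two-level FDR follows the reported workflow: Benjamini–Hochberg across
the 90 nodes within each nodal measure for the omnibus tests, and
across the three contrasts within each post-hoc family.  Global
measures are reported without across-feature adjustment, matching the
convention of reading the five global tests at uncorrected p-values.
Post-hoc tests run on all features by default; `posthoc = "survivors"`
restricts them to omnibus-FDR survivors, since the original order of
operations is ambiguous.  Zero-variance features are skipped with a
warning rather than failing the run.  Adjusted group means are
least-squares means — the model prediction per group with every
covariate (including the 0/1 sex code) held at its grand mean — with
t-based 95% intervals (the published figure does not state its
whisker level; 95% is the package default).

Calibration is tested, not assumed: under a null in which the outcome
depends on the confounded covariates but not on group, the
Freedman–Lane rejection rate at $\alpha = 0.05$ over 500 replicates of
500 permutations must stay inside the binomial 95% band
$[0.031, 0.069]$.

## Partial correlations

`partial_correlation(x, y, Z)` residualizes both variables on
(intercept + covariates) and returns the Pearson correlation of the
residuals; the p-value uses the t transform
$t = r\sqrt{(n-2-q)/(1-r^2)}$ on $n-2-q$ degrees of freedom.  The FDR
family is the 90 nodes within one (group × score × nodal measure)
triple — the only family structure the reported tables state — and
global measures stay unadjusted.  Missing scores are handled by
per-pair complete-case reduction with the effective n recorded; the
analysis runs in each patient group separately by default (HOA
correlations are computable but off by default).  Between-group
contrasts of correlations use the Fisher z method and are descriptive
only: at these sample sizes (~26 per group) they are underpowered, and
the tests treat them accordingly.

## The demographic-table machinery

A moment-matched sample is an affinely rescaled normal draw whose
sample mean and (n−1) standard deviation equal a printed
mean ± SD *exactly*.  Any statistic that depends on the data only
through per-group (n, mean, sd) — the pooled t and the one-way F — is
then invariant to the underlying draw, which makes summary statistics
in published demographic tables recomputable from the table alone.
`reproduce_table1()` does this for every row and compares with the
printed values at 1% relative tolerance (printed summaries are rounded
to two decimals).

Two quirks surfaced and are reported honestly rather than patched:
the sex row's χ² values match the *uncorrected* Pearson statistic even
though the table footnote says Yates (the package default is therefore
uncorrected, with a `yates` flag available); and several pairwise t
statistics match only in magnitude, the printed sign convention being
inconsistent across rows, so the output carries both signed and
magnitude agreement columns.  One row (the word-list recall z-score)
appears to carry a sign typo in its printed group mean and does not
reproduce; a few verbal-fluency rows deviate by a few percent,
consistent with unreported per-test missing data in the original
cohort.

## What the synthetic cohorts emulate — and what they do not

`sim_config()` defaults encode the study conditions: groups of
21/26/27; age and education drawn per group from the published
moments; sex from the published proportions; 90-node networks at edge
density 0.30 with log-normal edge weights (median ≈ 40, heavy right
tail) so nodal strengths land in the published ~600–2700 range; an age
leak of −0.8% weight per year producing realistic covariate
confounding; a planted additive strength effect of 11 weight units per
incident edge at the left calcarine in the amyloid-positive group
(sized from the published ~290-unit strength gap spread over ~27
incident edges); and one cognitive score linked to the right
mid-cingulum's regional efficiency-like channel at partial r = 0.5 in
one group.  Score links solve the slope analytically: with conditional
score SD $v$ and target correlation $r$, the measure contributes
$rv$ of SD and the residual noise $v\sqrt{1-r^2}$; targets whose
implied noise falls below the configured floor are rejected with the
feasible bound.

The generator is deliberately simple where realism does not matter for
testing the statistics: all subjects share one template topology (so
degree and edge density have zero between-subject variance and are
skipped as degenerate by the group analysis — real tractography
networks vary in topology); edge noise is independent Gaussian
(real streamline counts have correlated, heteroscedastic error);
and there are no distance-dependent wiring rules beyond the geometric
template.  Passing recovery tests therefore demonstrates that the
*inference machinery* is correct and calibrated, not that it will
achieve any particular power on real data.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to
desk scale as a deliberate design choice: oracle equivalence on 200
random graphs with up to 6 nodes; exhaustive enumeration at n = 6;
type-I calibration with 500 replicates × 500 permutations at the
study's n = 74; planted-effect recovery over 20 seeds at full study
size with 1000 permutations; and partial-correlation recovery at
n = 2000.  The permutation engine evaluates all permuted outcomes as
one matrix product against precomputed thin-QR factors, which is what
makes these replicate counts cheap.  Degenerate inputs follow one
rule: validation errors name the violated invariant and the offending
subject or cell; degenerate *features* (zero variance) are skipped
with a warning; degenerate *statistics* (zero pooled variance with
unequal means) are errors or flagged infinities, never silent numbers.

## A worked example

```{r example, eval = FALSE}
st <- simulate_study(sim_config(), seed = 1)
metrics <- connectome_metrics(st$connectomes)

res <- run_nodal_group_analysis(metrics, st$subjects,
                                n_perm = 1000, seed = 1,
                                posthoc = "survivors")
res %>% filter(scope == "nodal", measure == "strength") %>%
  arrange(p_fdr) %>% head(3)

y <- metrics$value[metrics$measure == "total_strength"]
autoplot(adjusted_group_means(y, st$subjects))

corr <- run_correlation_analysis(
  metrics, st$subjects[, c("subject_id", "word_list_recall_z")],
  st$subjects
)
```

## Known limitations

* The pipeline is undirected and unsigned; directed or signed networks
  are out of scope, as are rich-club, modularity and betweenness.
* Parametric ANCOVA p-values are exposed only as a diagnostic column
  (`p_param`), never as primary output.
* Whether the original analysis permuted raw labels or residuals, and
  whether its global tests received any correction, cannot be
  determined from the available description; both permutation modes
  exist here with Freedman–Lane as the default, and global tests are
  left uncorrected.
* The synthetic generator's shared-template topology makes
  degree-based group tests degenerate by construction (see above).
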