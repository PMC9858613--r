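---
title: "Conditional independence maps for categorical cohort data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional independence maps for categorical cohort data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cohorts of children and young people presenting at a paediatric emergency
department (ED) in suicidal crisis are typically described by a few dozen
mostly binary variables: adverse childhood experiences (ACEs — abuse,
neglect, domestic violence, parental mental ill health, drug misuse,
criminality, separated parents), demographic flags (sex, special
educational needs, autistic traits), clinical history (mental-health
diagnoses, history of deliberate self-harm, CAMHS contact, previous ED
attendance for the same reason), and a couple of genuinely categorical
variables (the means of self-harm and the clinician-assigned risk band).
Mutual covariance is pervasive in such data, so a matrix of marginal
pairwise tests is misleading: most pairs are associated through third
variables.

A conditional independence map (CI-Map) addresses this by keeping an edge
between two variables only when their association survives conditioning.
The result is a sparse graph whose connected components are interpretable
clusters — in the emulated analysis, a person-centred cluster around
CAMHS contact, a household-risk cluster around neglect, a parental-risk
triangle, and a sex/means/risk cluster. `cimap` implements the full
pipeline plus a calibrated synthetic generator, so every stage is testable
without access to confidential patient records.

## Association statistics

All association strength is measured by plug-in mutual information in
bits:

$$\widehat{MI}(X,Y) \;=\; \sum_{x,y} \hat p(x,y)\,
  \log_2 \frac{\hat p(x,y)}{\hat p(x)\hat p(y)},$$

with $0 \log 0 \equiv 0$. The unit is a deliberate, documented choice: the
0.05–0.80 range of reported edge weights in this literature is consistent
with bits for binary variables (the maximum being the smaller marginal
entropy, at most 1 bit). Conditional MI is the stratum-weighted average
$\widehat{CMI}(X,Y\mid Z) = \sum_z \hat p(z)\, \widehat{MI}(X,Y \mid Z=z)$;
empty strata contribute zero.

Significance uses the likelihood-ratio (G) test through the algebraic
identity $G = 2 N \ln(2)\, \widehat{MI}$ (and its stratified analogue with
CMI), referred to a chi-square distribution with $(r-1)(c-1)$ degrees of
freedom per non-empty stratum. The asymptotic reference is trusted only
under a relaxed Cochran rule: at least 80% of expected counts $\ge 1$ and
all $\ge 0.2$. Sparser tables fall back to a stratified permutation test
(`y` shuffled within every conditioning stratum, add-one estimator
$p = (1 + \#\{MI^* \ge MI\})/(1 + B)$), which is exact-in-distribution and
deterministic given its seed. Classical follow-ups use Pearson chi-square
without continuity correction with $\phi = \sqrt{\chi^2/N}$ on 2×2 tables
and Cramér's $V$ otherwise; the no-correction choice matches the effect
sizes conventionally reported alongside such maps and keeps $\phi$
consistent with $\chi^2$.

## Skeleton search

The paper-scale description of the method — "every test repeated and
conditioned on all other variables" — is infeasible verbatim at
$n = 240$ with ~30 discrete variables: a full conditioning set induces
astronomically sparse strata. `learn_skeleton()` therefore uses the
standard bounded-order, neighbourhood-restricted scheme familiar from
stable constraint-based structure learning:

1. start from the complete undirected graph;
2. for conditioning-set sizes $s = 0, 1, \dots,$ `max_cond` (default 2):
   freeze the adjacency at the start of the level, and for every surviving
   pair test independence given every size-$s$ subset of the pair's common
   neighbourhood, removing the edge at the first non-rejection;
3. retained edges carry their marginal MI and the maximum p-value seen.

Freezing neighbourhoods per level and iterating pairs in sorted-name order
makes the result invariant to the column order of the input — the "stable"
contract, verified by a test. `max_cond` is exposed rather than
hard-coded because the exact conditioning depth of the original method is
not recoverable; 2 is the default at these sample sizes.

Multiple testing: the default is `alpha = 0.05` uncorrected, mirroring the
reporting convention of the emulated analysis. For structure-recovery
studies over hundreds of pairs this is the wrong operating point — with
~250 truly independent pairs, ~5% of them would survive at size 0 — so a
`correction = "bonferroni"` flag divides alpha by the number of variable
pairs (a fixed, order-invariant divisor). The package's own recovery
benchmarks use this flag. A Benjamini–Hochberg option is deliberately not
offered inside the sequential skeleton (BH needs the complete p-value set
up front); it is available for the flat follow-up table in `run_report()`.

Two numerical details matter in the permutation fallback inside the
skeleton. First, the number of permutations is scaled to the decision
threshold (at most $\lceil 50/\alpha_{\mathrm{eff}}\rceil$, floor 199):
beyond that the accept/reject decision gains no resolution. Second, the
fallback stops early once $(1+\text{exceedances})/(1+B)$ exceeds the
threshold — the add-one p-value is monotone in the exceedance count, so
the pruning decision is identical to the full run; only edges that are
*retained* need (and get) the full-resolution p-value.

## Orientation and acyclicity

The phrase "directed according to the relative strength of conditional
probabilities" admits many formalisations; the package uses a
total-variation asymmetry rule, chosen because it is deterministic,
symmetric in construction, and swappable behind one function:

$$\mathrm{score}(x \to y) \;=\; \max_{a,b}\;
  TV\!\left(\hat P(y \mid x=a),\; \hat P(y \mid x=b)\right),$$

the edge pointing towards the endpoint whose conditional distribution is
more strongly shifted. Parent levels with zero counts are skipped; if
fewer than two levels remain the edge stays unoriented. Ties (including
the exact tie produced by a deterministic copy) resolve to the
lexicographically smaller source.

`orient_and_acyclify()` then processes edges in decreasing MI (ties:
lexicographic) and reverses any edge whose preferred direction would close
a directed cycle; if both directions close cycles the edge is kept
unoriented and flagged. This greedy reverse-then-flag rule is not a global
optimum search — the emulated method says only that loops are removed —
but it is deterministic, explainable edge by edge, and guarantees an
acyclic oriented subgraph, which is property-tested over random cohorts.
Orientation is descriptive, not causal: for pairwise-calibrated edges the
sampled joint distribution is direction-free, and the asymmetry score
frequently orients against the generative direction. No v-structure or
Meek-rule logic is attempted.

## The synthetic generator

`study_network()` is a ground-truth DAG plus one CPT per variable,
calibrated so that the generating distribution reproduces the published
evidence exactly where it is printed:

* **Printed marginals** (female 160/240, known to CAMHS 154/240, previous
  attendance 58/240, history of self-harm 162/240, autistic traits 51/240,
  anxiety 43/240, low mood 40/240, other diagnosis 35/240, SEN 58/240,
  self-harm at presentation 83/240) are used as CPT marginals.
* **Printed edge weights** (0.80, 0.72, 0.24, 0.13, 0.12, 0.11, 0.10,
  0.09, 0.07, 0.06, 0.05, 0.03 bits) are hit exactly by construction.
* **Unprinted quantities** default to 0.15 (both prevalences and edge
  weights) and are flagged `published = FALSE` in the edge table. One
  deviation from that default was forced by arithmetic: the maximum MI of
  a binary pair is the smaller marginal entropy, and $H(0.15) \approx
  0.61$ bits cannot carry the 0.80- and 0.72-bit edges, so neglect, abuse
  and domestic violence use prevalence 0.30 ($H(0.3) \approx 0.88$).

Calibration solves three problems:

1. **Binary pair.** A 2×2 joint with fixed margins has one free parameter
   $p_{11} \in [\max(0, p_x+p_y-1), \min(p_x, p_y)]$; MI is zero at
   independence and strictly increasing towards each boundary, so
   `calibrate_pairwise_joint()` finds the target by monotone root-finding
   (`uniroot`, tolerance $10^{-9}$ bits, verified against a $10^{-6}$-step
   grid-scan oracle in the tests).
2. **Categorical pair** (sex→means, means→risk). The conditional matrix is
   moved along a fixed direction away from independence, $P_t(\cdot \mid
   k) = m + t D_k$, with $D$ projected to zero row sums and zero
   parent-weighted column sums so that every $P_t$ is stochastic and the
   child marginal is preserved *exactly* for all $t$; MI is again monotone
   in $t$ and root-found.
3. **Shared children** (low mood, with both CAMHS and previous attendance
   as parents; parental crime, with both other parental variables).
   Pairwise root-finding does not apply, so the CPT logits are fitted by
   deterministic BFGS to match the child marginal and *both* pairwise MI
   targets simultaneously (residuals checked below $10^{-6}$ at build
   time). This matters for structure recovery: if low mood depended on
   CAMHS only, its printed link with previous attendance would be an
   indirect association and correctly pruned by conditioning.

Age is a discretised truncated normal on 8–16 with mean 13.5 and SD 1.42.
The truncation is asymmetric (13.5 sits 5.5 below the upper bound but only
2.5 above the lower), so the model mean is ≈13.44 rather than 13.5; this
is an honest property of the stated model, not a bug, and simulated means
land within ±0.1 of the published 13.5. SEN is included as an isolated
node: the emulated analysis explicitly found no SEN/mental-health link.

Sampling is ancestral: variables are drawn in topological order, one
`runif(n)` vector per variable, from the Mersenne-Twister generator (the
algorithm is recorded in the map provenance so reimplementations can
document divergence). Identical `(network, n, seed)` yields byte-identical
CSV output.

What the generator does *not* emulate: the real joint distribution beyond
printed marginals and MI values (everything else is the product structure
of the DAG), missingness (synthetic records are complete), COVID-era
attendance drift, and any latent confounding. Passing recovery tests
therefore demonstrates that the pipeline recovers *this class* of sparse
categorical dependence structures at these sample sizes — not that it
would recover the true clinical structure from 240 records.

## The deterministic descriptive fixture

`reference_cohort()` reproduces the published descriptive table
cell-for-cell by block fill: previous attenders first, each variable
assigned its attended-column counts in level order, then the remaining
records take overall-minus-attended counts. The printed table is
internally inconsistent in one place: every attended sub-column sums to
57, while the attended total row prints 58. No 240-record table can
satisfy both, so the fixture follows the sub-columns (57 attenders),
which reproduces every per-variable cell in both columns exactly; the
implied joint for sex × previous attendance is then
[[45, 115], [12, 68]]. Ages are filled deterministically so that the
overall mean is exactly 13.5 (range 8–16) and the attenders' mean is
13.70. Percentages follow the printed convention: share of *total* sample
even within the attender column, to one decimal place with half-up
rounding (the printed 18.8% for 45/240 = 18.75% rules out half-even).

The block fill makes within-column joints deterministic and artificial;
the fixture is for descriptive-table arithmetic and smoke tests, not for
structure learning.

## Degenerate inputs and tie-breaks

* Empty cohorts summarise to zero counts with percentages reported as 0
  and a `zero_n` flag; `n = 0` contingency tables are errors.
* Crosstabs use pairwise-complete records and report the exclusion count;
  a pair with no complete records raises a typed `cimap_empty_table`
  error.
* Zero-margin levels are an error (naming the level) in
  `chi_square_effect()`; in the G-test they route to the permutation
  fallback via the expected-count rule.
* All tie-breaks — edge processing, orientation, pair iteration — are
  lexicographic on variable names; every stochastic step takes an explicit
  seed, and per-test seeds inside the skeleton are derived from the pair
  and conditioning-set *names* so that they too are order-invariant.

## Problem sizes used by the test-suite benchmarks

The package's own verification uses: n = 100,000 samples for MI recovery
on calibrated edges (±0.02 bits), n = 50,000 for marginal recovery
(3 binomial SEs), 20 seeds × n = 10,000 for skeleton precision/recall
(≥ 0.95 with the Bonferroni flag), 1,000 null simulations at n = 500 for
conditional-test calibration (type-I in [0.03, 0.07]), and 1,000 random
tables for oracle equivalence of MI, G, chi-square and effect sizes at
relative error < 1e-9. These sizes were chosen as the smallest at which
the corresponding asymptotic claims are expected to hold cleanly.

## Known limitations

* Orientation is a descriptive asymmetry heuristic; it does not identify
  causal direction and often disagrees with the generative direction of
  the synthetic network.
* The skeleton's bounded conditioning (default order 2) can in principle
  retain edges that only a larger conditioning set would remove.
* Plug-in MI is upward-biased at small n (order $(r-1)(c-1)/(2N\ln 2)$);
  no bias correction is applied because significance, not the point
  estimate, drives pruning.
* The permutation fallback's p-values are granular at $1/(B+1)$; with
  heavy correction and small `n_perm` a sparse pair may be unretainable.
* The real cohort is confidential; nothing here estimates its full joint
  distribution, and the published chi-square follow-ups are recomputed
  from data rather than matched to printed values whose denominators are
  not reconstructible.
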