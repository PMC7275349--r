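---
title: "Methods: signature reversal, pathway perturbation, and the synthetic benchmark"
author: "sigreverse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature reversal, pathway perturbation, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

## The problem and the model

Drug repositioning by signature reversal rests on a simple hypothesis:
if a disease up-regulates a set of biological processes and
down-regulates others, then a drug whose transcriptomic perturbation
pushes those same processes in the *opposite* directions is a
candidate therapeutic. `sigreverse` implements this idea in three
layers.

**1. GWAS contextualization.** Differential-expression signatures are
noisy and tissue-confounded; genetic associations supply independent
disease context. Each disease's DEG gene set is tested against each
disease's GWAS gene set with a one-sided Fisher's exact test
(hypergeometric upper tail $P(X \ge |A \cap B|)$), all pairs are
adjusted jointly by Benjamini–Hochberg, and a disease keeps the
intersection of its own DEG and GWAS sets when the same-disease pair
has $q \le 0.05$. Drug signatures, which carry no intrinsic disease
context, pass a much more stringent $q \le 10^{-10}$ against the
disease's GWAS genes, and a third Fisher stage intersects the
surviving drug sets with the disease-specific sets ($q \le 0.05$).
The cascade is optional end to end (`filter_stages` in
`run_pipeline()`): all three stages give the most conservative gene
sets; skipping them scores every drug against every disease, which is
what ROC validation needs.

**2. Signed topology-based pathway enrichment.** Gene-level
signatures are reduced to pathway-level direction calls. For each
pathway with signed, directed edges ($\beta = +1$ activation, $-1$
inhibition), the perturbation factor of gene $i$ solves

$$PF(i) = \Delta E(i) + \sum_{j \to i} \frac{\beta_{ij}\,PF(j)}{N_{ds}(j)},$$

with $N_{ds}(j)$ the out-degree of $j$ (self-loops count once). We
solve $(I - B_{norm})\,PF = \Delta E$ densely, refusing systems whose
smallest singular value is below $10^{-10}$ (such pathways are
skipped, not guessed). The net accumulation $Acc = PF - \Delta E$ sums
to the total accumulation $t_A$; its sign is the pathway's direction.
Significance combines two independent components: an
over-representation hypergeometric tail $p_{NDE}$ and a bootstrap
$p_{PERT}$ obtained by reassigning the observed nonzero $\Delta E$
values to random member subsets of the same size. The bootstrap tail
is median-centred and uses the $(1 + k)/(1 + n_{boot})$ estimator so
it is never exactly zero; with the factorized system all replicates
are a single multi-RHS solve, so the default $n_{boot} = 2000$ is
cheap (tests and the benchmark use 200, which already gives a
$p$-value resolution of 1/201 — finer than any decision threshold in
the workflow). The combination is the exact product tail
$p_G = c - c\ln c$, $c = p_{NDE}\,p_{PERT}$, adjusted by BH *within
each entity's run*: each disease's or drug's enrichment is its own
testing family.

**3. Anti-correlation scoring.** Pathways with $q_G < 0.05$ and a
nonzero direction become a $\pm 1$ signature vector. Drug and disease
vectors are materialized over the union of their supports (zeros
elsewhere) and compared by Pearson correlation; a drug whose vector is
the negation of the disease's scores $-1$. The shortlist keeps
correlation $\le -0.4$ and coverage of strictly more than 50% of the
disease's dysregulated pathways; two-drug combinations (elementwise
sign-of-sum, conflicts cancel) use $\le -0.50$ and $> 80\%$. A
`mimic` mode keeps the strong *positive* correlations instead —
useful for finding drugs that reproduce a phenotype. Levenshtein edit
distance over the ordered $\{-1, 0, +1\}$ strings is reported as an
alternative dissimilarity but never drives the default ranking.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `q_disease_gwas` | 0.05 | BH threshold, disease DEG vs GWAS overlap |
| `q_drug_gwas` | 1e-10 | BH threshold, drug DEG vs GWAS overlap |
| `q_triple` | 0.05 | BH threshold, three-way overlap |
| `q_pathway` | 0.05 | FDR for a pathway to enter a signature vector |
| `corr_max` / `affected_min_pct` | −0.4 / 50 | single-drug shortlist ($\le$ / strict $>$) |
| `pair_corr_max` / `pair_affected_min_pct` | −0.50 / 80 | drug-pair shortlist |
| `n_boot` | 2000 | bootstrap replicates (perturbation null, AUC CI) |
| `universe_policy` | observed_union | Fisher background (see below) |
| `index_policy` | union | index set for the correlation |

Two genuinely open design points deserve justification:

* **Fisher background.** No external annotation defines "all genes",
  so the default universe is the union of genes observed in the two
  tables being compared — self-consistent and computable offline. A
  fixed size or an explicit gene list can be supplied instead; with
  small, dense inputs the observed union is small and the same overlap
  is judged less surprising, which is the conservative direction.
* **Correlation index set.** Correlating over the union of supports
  penalizes drugs with large off-disease pathway footprints; the
  `disease_only` policy ignores them. Union is the default because the
  comparison is meant to be a whole-signature one. The boundary
  semantics of the shortlist are $\le$ on correlation and strict $>$
  on coverage.

Undefined correlations are first-class citizens, not errors: a
disease (or drug) whose significant pathways all share one sign has a
constant vector, zero variance, and no Pearson correlation. Such
pairs are recorded with `NA` and excluded from ranking and from the
ROC. This happens in practice under the GWAS-filtered cascade, where
a disease may keep too few pathways for both signs to survive.

## The synthetic benchmark

Real inputs for this workflow are multi-gigabyte snapshots of
perturbation libraries, expression atlases and GWAS compilations. The
package instead ships a generator (`generate_benchmark()`) whose
world every stage can be validated against, because the answers are
planted:

* **Pathways**: 50 random graphs over a 2,000-gene universe, 10–30
  members each, weakly connected through a random spanning tree plus
  extra edges (the connectivity guarantees a nontrivial propagation
  system), 25% inhibitory edges.
* **Diseases**: 5 diseases, each driving 10 pathways — half up, half
  down. Balance is enforced because an all-one-sign disease has a
  constant signature vector and no defined correlations; real complex
  diseases dysregulate in both directions. Within driver pathways,
  genes acquire GWAS associations at rate 0.5 and DEGs at rate 0.8
  (sign = planted pathway sign, flipped with probability 0.05,
  $|\Delta E| \sim U(0.5, 3)$ so enrichment sees nondegenerate
  magnitudes); background genes at rate 0.01 for both modalities.
* **Drugs**: per disease, one *inverter* (the disease's DEG rows with
  effects negated — the pipeline must rediscover the pathway-level
  inversion, it is never handed pathway labels) and one *mimicker*
  (effects copied), plus 20 unrelated drugs. Unrelated drugs are
  pathway-structured — each perturbs its own random driver pathways by
  the same mechanism as a disease — rather than uniform gene draws: a
  drug is a biological perturbation, and uniform draws would produce
  empty pathway signatures and hence no defined correlation for any
  negative control, leaving the ROC without negatives.
* **Labels**: the indications table marks each inverter as trialed
  for its disease; nothing else is labeled.

Everything is a pure function of the configuration's seed; rerunning
with the same seed reproduces every file byte for byte.

For null calibration of the ROC the generator offers
`coupled = FALSE`: inverters and mimickers are replaced by
independently drawn structured signatures while the labels stay. This
is the right null because the planted drugs are *constructed* from
the disease signature — merely weakening enrichment rates cannot make
them uninformative (an exact negation stays perfectly anti-correlated
at any rate), it only makes all scores undefined. Decoupling is
equivalent to permuting labels. The null run uses 16 diseases, chosen
a priori so the null AUC's standard deviation (≈0.07 with 16
positives among ~800 scored pairs) makes the $0.5 \pm 0.15$
calibration band a ±2-standard-deviation statement.

### What the benchmark does not emulate

Linkage disequilibrium and gene-length confounding in GWAS, eQTL
structure, tissue and cell-line specificity, dose–response of
perturbation libraries, correlated pathway cross-talk beyond shared
members, and identifier messiness (the mapping-table machinery is
exercised with synthetic mappings only). Passing the benchmark shows
the machinery is correct and the planted effect sizes recoverable; it
does not certify performance on real compendia.

## Numerical choices and degenerate inputs

* Perturbation systems are solved by LAPACK dense solve after an SVD
  singularity check at $10^{-10}$; genes with no incoming edges get
  $Acc \equiv 0$ exactly.
* The bootstrap p-value cannot be 0 or exceed 1 by construction; an
  all-zero on-pathway $\Delta E$ yields $p = 1$, $t_A = 0$, and an
  edgeless pathway yields $p = 1$ (every replicate's $t_A$ is 0).
* Duplicate (entity, gene) measurements collapse to the
  maximum-|effect| row (ties: larger signed effect, then input
  order) — a declared convention chosen so the strongest perturbation
  survives; identifier harmonization applies the same rule after
  mapping and passes already-canonical identifiers through, making it
  idempotent.
* Rankings break ties by correlation, then coverage, then
  lexicographic drug key, so output order is deterministic.
* Mann–Whitney uses exact enumeration for combined $n \le 20$ without
  ties and the tie-corrected normal approximation otherwise; the ROC
  AUC uses midranks (ties count 1/2).

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the default benchmark
(2,000 genes / 50 pathways / 5 diseases / 30 drugs, $n_{boot} = 200$),
a 16-disease decoupled world for null calibration, 500-replicate
uniformity checks of the bootstrap p-value, exhaustive oracle sweeps
of the hypergeometric tail up to a 12-gene universe, and edit-distance
enumeration up to length-8 index sets. These sizes make the whole
suite run in about a minute while leaving every decision threshold
well inside the resolution of the statistics involved.

## Known limitations

Combinations beyond two drugs are out of scope (the pair count alone
is quadratic). The enrichment model assumes the linear propagation
system is an adequate summary of pathway logic — feedback loops that
make $(I - B_{norm})$ singular are skipped rather than modeled. BH
families are per-stage and per-entity; other pooling choices are
defensible and would change borderline calls. The Fisher background
never sees genes absent from the input tables, so absolute
significance levels are comparable only within a run.
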