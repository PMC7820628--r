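---
title: "Scoring tissues of action for fine-mapped GWAS signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tissues of action for fine-mapped GWAS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toascore)
```

## The problem and the model

A fine-mapped GWAS signal is a 99% credible set: a collection of SNPs, each
carrying a posterior probability of association (PPA), that together explain
at least 99% of the evidence for one conditionally independent association.
The question this package answers is *which tissue the signal most likely
acts in*, by distributing each SNP's PPA over a panel of evaluated tissues
in proportion to the regulatory evidence at its position.

The evidence combines three layers:

1. **Chromatin states.** Each tissue contributes a genome segmentation into
   states (active TSS, strong/weak enhancer, transcription, quiescent,
   repressed, ...). A SNP overlapping state $a$ in tissues
   $\{t_1,\dots,t_k\}$ contributes weight $w_{a,t}/k$ to each — sharing an
   element across $k$ tissues dilutes the per-tissue evidence by $k$.
2. **Enrichment weights.** $w_{a,t} = 2^{\mathrm{log_2FE}(a,t)}$, the
   exponentiated genome-wide log2 fold enrichment of trait-associated SNPs
   in that annotation (e.g. fgwas output). Coding sequence (CDS) is a single
   genome-wide annotation, so its weight is tissue-invariant. Because every
   SNP's vector is normalized before PPA partitioning, rescaling *all*
   weights by a common factor changes nothing; only relative enrichments
   matter.
3. **Expression specificity.** For coding SNPs the tissue indicator is
   replaced by the gene's expression specificity score (ESS): the per-tissue
   median TPM divided by the sum of those medians over evaluated tissues.
   ESS rows of expressed genes sum to one, so the CDS weight is spread over
   tissues in proportion to where the gene is expressed.

Per SNP $j$: $s_{j,a,t} = w_{a,t}\, m(j,a,t) / \sum_i m(j,a,i)$ and
$s_j = \sum_a s_{j,a}$. Per signal $c$ with credible SNPs $J$:

$$\tau_c = \sum_{j \in J} P_j \frac{s_j}{\sum_t s_{j,t}}, \qquad
U_c = \sum_{j \in J} P_j - \sum_t \tau_{c,t}.$$

The partition is exact: tissue scores plus the unclassified residual $U_c$
reproduce the cumulative PPA to floating-point accuracy (the package asserts
1e-9 everywhere; in practice the error is at machine epsilon). $U_c$ absorbs
PPA of SNPs overlapping no *included* annotation — by default quiescent and
repressed-polycomb states are excluded from scoring, while all
TSS/enhancer/transcription states are included; the list is an argument
(`included_states`) because both choices are scientifically defensible and
weak transcription in particular carries a large share of PPA in real data.

## Assumptions worth stating

- Every variant is treated as a single base at its reported position; the
  credible-set input is 1-based, chromatin states are 0-based half-open
  (BED), and the overlap rule is `start <= pos - 1 < end`.
- Within one tissue a chromatin segmentation never overlaps itself; the
  readers enforce this and refuse to proceed otherwise.
- Credible sets whose PPAs sum below 1 are *not* renormalized: $\tau + U$
  equals the printed cumulative PPA, whatever it is.
- Chromosome naming styles (`"chr1"` vs `"1"`) must agree across inputs;
  mismatches are an error, never silent non-overlap.

## Derived statistics and the classifier

**SSD.** Tissue specificity of a profile is the sum of squared differences
over unordered tissue pairs, computed on the tissue scores only. The
"sum of squared distances" phrase admits several readings; the pairwise
definition is the one under which a distance *between* TOA scores is well
defined, and it is what `ssd()` implements (equal scores give 0; a pure
single-tissue profile gives 3 with four tissues).

**Coding score.** The cumulative PPA a signal owes to coding variants. We
use the share-weighted version — $\sum_j P_j \cdot (\text{CDS part of } s_j)
/ (\sum_t s_{j,t})$ — rather than the cruder sum of PPA over any
CDS-overlapping SNP, because a SNP can overlap both CDS and chromatin
annotations; the share-weighted version is what the conservation identity
supports. The co-expression stage excludes signals with coding score at or
above 0.1.

**Classifier.** Arg-max tissue above a threshold in $\{0, 0.2, 0.5, 0.8\}$;
with the shared mode on, a gap of at most 0.10 between the top two scores
yields `"shared"` (the shared call still requires the top score to meet the
threshold — otherwise a signal could be "shared" on negligible evidence).
The gap rule is applied to the raw $\tau$, not $\tau/(1-U)$. Exact ties are
"shared" when allowed; with sharing off they break by a fixed tissue order
with a warning, keeping the classifier deterministic. Shared signals are
tiered by fine-mapping resolution: single-SNP sets (tier 1), max PPA
$\ge 0.5$ (tier 2), otherwise tier 3.

**A SNP in several genes' CDS** takes the mean of their ESS vectors —
symmetric, order-independent, and degrades gracefully when one gene is
missing from the expression panel (missing genes contribute zero, with a
warning).

## Permutation statistics

All enrichment tests share the add-one empirical p value
$p = (n_{\text{extreme}} + 1)/(N + 1)$, whose floor is $1/(N+1)$, and all
take a mandatory seed that is recorded in the output row.

- **Tissue-specific eQTLs:** specific(t) = significant(t) minus every other
  tissue's significant set; observed overlap of tissue-assigned index SNPs
  vs size-matched SNP sets. The matching strategy is injectable: uniform
  draws from a supplied universe by default, or stratified draws matching
  covariate bins (e.g. MAF deciles) — the appropriate covariates depend on
  what the user can supply, so the package does not hard-code them. eQTL
  identity is the SNP id by default; SNP–gene pairs work identically if the
  caller encodes them as `"snp:gene"` strings. Inputs are assumed
  FDR-filtered; `filter_eqtls_fdr()` offers a Benjamini–Hochberg
  approximation for users holding only nominal p values.
- **Physiology clusters:** null sets resample equally many signals from the
  fine-mapped universe, without replacement, 10,000 times by default.
- **GWAS catalog:** a signal's index SNP and LD proxies collapse to a
  single overlap per trait (guarding against local-LD double counting);
  null signal sets re-expand to their own proxies — each resampled signal
  carries its proxy set, mirroring how the observed statistic is built.
- **Expression similarity:** genes are filtered (a gene must reach 0.1 TPM
  in at least half the samples of at least one tissue — the permissive
  reading, which retains tissue-specific genes, the very objects of
  interest), then ranked globally by mean expression. Null genes are drawn
  per query gene from the ±100 global-rank window (inside the ±150
  background; the narrower window makes the background constraint
  automatic when applied per gene, which is the stricter of the two
  readings and the default). The per-tissue statistic is the within-tissue
  rank sum; small rank sums mean high expression, so the lower tail is
  significant and the enrichment factor is null-mean/observed.
- **Co-expression (msr):** mean squared pairwise Spearman correlation
  within a tissue, against equal-size draws from the pool of genes proximal
  to the full signal list; invariant under monotone transformations of
  expression; zero-variance genes are dropped with a warning.

Nearest-gene assignment measures distance from the index SNP to the gene
TSS — the conventional anchor — with ties broken by gene id.

## The synthetic generator: what it emulates, and what it does not

`generate_fixture()` builds a 1 Mb single-chromosome genome with
enhancer-scale elements (mean 600 bp, mean gap 1 kb), each carrying one
active state and a tissue-membership set: 30% of elements are shared by two
or more tissues by default, the rest are tissue-specific, and each tissue's
map is completed with a quiescent filler so it is a genuine segmentation.
Credible sets (100 signals by default, geometric sizes with mean 20,
Dirichlet-like PPAs) plant a known tissue per signal: 80% of credible SNPs
land in elements active in the planted tissue, the rest anywhere. Planted
SNPs are placed in non-coding positions of their host element, since the
construction is meant to model regulatory signals — a coding overlap would
legitimately re-route the score through the gene's expression profile. The
expression panel (300 genes, 20 samples per tissue, Poisson counts around
tissue-skewed log-normal means) feeds ESS and the co-expression stages, and
companion eQTL/cluster/proxy/trait tables are planted consistently with the
ground truth.

Defaults are deliberate: the shared-element fraction and credible-set sizes
produce the mix of clean, shared and diluted signals on which the scoring
problem is non-trivial (planted-tissue recovery sits near 85%, not 100%),
while single-SNP fully specific configurations recover the planted tissue
exactly, as the construction forces.

What the generator does **not** emulate: linkage disequilibrium between
credible SNPs (positions are placed independently), realistic chromatin
state length distributions and genome-wide state frequencies,
between-sample expression covariance, population structure, or multiple
chromosomes. Passing tests on fixtures therefore demonstrate the
*mathematics and plumbing* are right — exact PPA conservation, correct
interval algebra, correctly calibrated permutation nulls — not that the
biological signal in any real dataset is recoverable at a given rate.

## Numerical choices

- Conservation and round-trip tolerances are 1e-9 absolute; weight-scale
  invariance is asserted at 1e-12.
- Median over an even number of samples is the midpoint median
  (`stats::median`).
- Credible-set construction breaks PPA ties by lexicographic SNP id;
  sets whose total PPA misses 0.99 retain all SNPs and are flagged rather
  than dropped.
- Degenerate permutation cells: a zero null mean with a positive observed
  count reports fold `NA` (the p value remains valid); zero observed with
  zero null mean reports fold 0.
- All randomized functions seed locally (`withr::with_seed`), so no global
  RNG state leaks between stages and identical configs give byte-identical
  artifacts.

## Problem sizes

The test suite and the acceptance script run on 100-signal fixtures over a
1 Mb genome (two fixtures, 200 credible sets, for the conservation and
oracle-equivalence properties), 1,000–4,000 permutations for the
enumeration-matched enrichment checks, and 500 replicates for the
calibration check of the empirical p value — sizes at which the exhaustive
oracles (per-base interval labeling, naive per-SNP double loops, full
subset enumeration) remain exact and fast.

## Limitations

Enrichment estimation itself (fgwas), eQTL mapping, LD/proxy computation
and fine-mapping are out of scope: their outputs are inputs here. The
matched-SNP null for the eQTL test is only as good as the supplied universe
or covariate bins. Scores are relative to the evaluated tissue panel — a
signal acting in an unprofiled cell type will surface as unclassified (or
be misattributed to a correlated profiled tissue), and the unclassified
score is therefore a first-class output, not an error state.
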