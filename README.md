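# toascore

Tissue-of-action (TOA) scores for fine-mapped GWAS signals.

Most trait-associated variants are non-coding, and interpreting them requires
knowing *which tissue* a signal acts in — basing follow-up on islet data for a
variant that operates in liver misdirects experimental effort. `toascore`
addresses this for any complex trait with per-tissue epigenome maps: it
integrates Bayesian fine-mapping output, tissue-specific chromatin-state
segmentations, and gene-expression specificity into one probabilistic tissue
score per association signal. It is aimed at statistical geneticists working
downstream of fine-mapping (e.g. type 2 diabetes signals scored against
pancreatic islet, adipose, liver, and skeletal-muscle annotations).

## The model

For each SNP *j* in a 99% genetic credible set, with posterior probability of
association *P_j*, and each annotation *a* (chromatin states plus coding
sequence, CDS), the tissue component is

    s_{j,a,t} = w_{a,t} * m(j,a,t) / sum_i m(j,a,i)

where `w_{a,t} = 2^log2FE(a,t)` is the genome-wide enrichment weight and the
mapping value `m(j,a,t)` is 1 if SNP *j* overlaps state *a* in tissue *t*
(so a state shared by *k* tissues splits each weight by *k*), the gene's
expression specificity score (ESS) `eps_{g,t}` for a CDS overlap, and 0
otherwise. ESS is the per-tissue median TPM divided by its sum over evaluated
tissues, so ESS rows of expressed genes sum to 1. Summing over annotations
gives the SNP vector `s_j`, and the signal's TOA scores partition its PPA
exactly:

    tau_c = sum_{j in J} P_j * s_j / sum_t s_{j,t}
    U_c   = sum_j P_j - sum_t tau_{c,t}

with the unclassified score *U_c* absorbing PPA of SNPs that touch no
included annotation (e.g. quiescent or repressed chromatin) in any tissue.
A rule-based classifier assigns a signal to its arg-max tissue above a
stringency threshold (0.0 / 0.2 / 0.5 / 0.8), calls it `"shared"` when the
top two scores are within 0.10, and `"unclassified"` otherwise. Permutation
machinery (tissue-specific eQTL, physiology-cluster and GWAS-catalog
enrichment; rank-matched expression-similarity and Spearman co-expression
tests) validates the assignments, all with add-one empirical p values
`(n_extreme + 1) / (N + 1)`.

## Worked example

Everything is testable offline through the built-in generator, which plants
a known tissue of action per signal:

```r
library(toascore)

fx <- generate_fixture(fixture_config(seed = 1))   # 100 signals, 4 tissues
profiles <- score_fixture(fx)                      # ESS + weights + TOA
head(profiles[, c("signal_id", "islet", "adipose", "liver", "muscle",
                  "unclassified", "max_ppa", "n_snps", "ssd")])
#>    signal_id  islet adipose  liver muscle unclassified max_ppa n_snps   ssd
#> 1 signal_001 0.7096  0.0326 0.1311  0.040       0.0868  0.1696     14 1.259
#> 2 signal_002 0.0863  0.4680 0.2561  0.162       0.0274  0.2288      9 0.328
#> 3 signal_003 0.1203  0.1186 0.3274  0.090       0.3437  0.3253     12 0.145
#> 4 signal_004 0.1029  0.1416 0.1220  0.622       0.0112  0.0924     34 0.754
#> 5 signal_005 0.4561  0.1152 0.0749  0.141       0.2125  0.2186     19 0.367
#> 6 signal_006 0.2010  0.4853 0.1061  0.156       0.0511  0.1152     39 0.346

asn <- classify_signals(profiles, threshold = 0.2, allow_shared = TRUE)
table(asn$label)
#>  adipose    islet    liver   muscle   shared unclassified
#>       23       22       18       22       13            2

recovery_rate(fx, profiles = profiles)   # fraction matching planted truth
#> [1] 0.83
```

Each row of `profiles` partitions that signal's cumulative PPA: the four
tissue columns plus `unclassified` sum to `cumulative_ppa` exactly, `ssd` is
the sum of squared pairwise differences between the tissue scores (larger =
more tissue-specific), and `coding_score` is the PPA share attributable to
coding variants. On this fixture the classifier recovers the planted tissue
for 83% of signals at the 0.2 threshold — the remainder are diluted by
shared regulatory elements and low-resolution credible sets, as in real
data.

Real inputs enter through `read_credible_sets()` (with a column `dialect`
for consortium-specific headers), `read_state_maps()`, `read_cds()` and
`read_expression()`; `run_pipeline()` (or the thin wrapper in
`inst/cli/toascore.R`) chains the stages from a YAML config.

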