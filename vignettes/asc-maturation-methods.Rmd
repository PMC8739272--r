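---
title: "Methods: multi-omic analysis of antibody-secreting cell maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic analysis of antibody-secreting cell maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascmature)
```

# The scientific setting

Antibody-secreting cells (ASCs) minted in the blood after vaccination are
short-lived unless they reach the bone marrow (BM), where a subset matures
into long-lived plasma cells (LLPCs) that secrete antibody for decades.
`ascmature` implements the statistical layer of a maturation study that
compares flow-sorted blood ASC subsets (Pop 2: CD19+CD38++CD138−, Pop 3:
CD19+CD38++CD138+) with BM subsets (Pop A, Pop B, and the LLPC compartment
Pop D, CD19−CD38+CD138+) across four readouts: transcriptome (RNA-seq
counts), chromatin accessibility (ATAC-seq peak counts), B-cell receptor
(BCR) repertoire (bulk VDJ sequencing at two yearly timepoints), and cell
morphometry (areas and mitochondria counts from stained images).

A design feature with statistical consequences: blood and BM samples come
from *different* donors. Patients are therefore nested within compartment,
each patient contributing one sample per population of their own
compartment only. This unbalanced, nested structure is exactly what the
mixed model and the synthetic generator reproduce.

# Differential expression: per-gene mixed-effects ANOVA

Expression values are analyzed on a log2 scale after median-of-ratios
library normalization. For each gene,

$$ y_{ij} = \mu + \alpha_{\mathrm{pop}(ij)} + b_{\mathrm{patient}(ij)} + \varepsilon_{ij},
\qquad b \sim N(0, \sigma_b^2),\ \varepsilon \sim N(0, \sigma_e^2), $$

with population a fixed effect and patient a random intercept. The fit is
restricted maximum likelihood, profiled down to the one-dimensional
variance ratio $\lambda = \sigma_b^2/\sigma_e^2$ and optimized to a
tolerance of 1e-8 with $\sigma_b^2$ floored at zero. Because the design is
shared by all genes, the eigendecomposition of the patient relatedness
matrix $ZZ^\top$ is computed once and reused, which is what makes
transcriptome-wide fitting cheap. `lme4::lmer()` reproduces these fits;
the test suite uses it as an independent oracle but the package never
calls it in the pipeline.

Pairwise population contrasts use the Tukey–Kramer statistic
$q = |m_a - m_b| / \sqrt{(v_a + v_b)/2}$ on the model-based means and
their estimated variances, referred to the studentized range distribution
with $k$ = number of populations. The error degrees of freedom are the
containment (residual) df, $n - \mathrm{rank}([X\,Z])$; Satterthwaite-type
approximations are deliberately out of scope because the containment rule
is deterministic and reproducible. When patients are confounded with
residuals (one observation per patient), the fit collapses to a one-way
ANOVA and with $k = 2$ balanced groups the Tukey p-value equals the pooled
two-sample t-test exactly — both collapses are tested.

P-values are Benjamini–Hochberg corrected **across genes within each
pairwise comparison** (a pooled-family alternative is available via
`pool_comparisons = TRUE`). A gene is a DEG when q < 0.05; the in vitro
culture design additionally requires a fold change of 2
(`min_abs_log2fc = 1`, compared inclusively). Low-expression genes are
removed ahead of normalization when their total count over all samples is
below 150 (ex vivo) or 1000 (in vitro), boundaries applied as "keep if
total ≥ threshold".

# Differential accessibility: NB conditional exact test

Peak counts are overdispersed, so two-group comparisons use a negative
binomial conditional exact test rather than a per-peak linear model. With
normalized group library sizes $L_A, L_B$ and dispersion $\phi$, the group
sums are modelled as NB with size parameters $L_A/\phi$ and $L_B/\phi$
sharing one success probability; conditional on the total $t$, the
distribution of one group's sum is negative-hypergeometric and free of the
nuisance mean. The two-sided p-value sums all outcomes whose conditional
probability does not exceed the observed one (the `binom.test` convention),
and at $\phi = 0$ the test reduces *exactly* to the binomial test of $a$
successes in $t$ trials at proportion $L_A/(L_A+L_B)$. Group size
parameters proportional to library size make this reduction exact under
unequal libraries; when size factors differ within a group the NB
representation of the group sum is an approximation, which is the price of
keeping the conditional law nuisance-free.

Dispersions come from a pooled method-of-moments estimator on
size-factor-normalized counts ($\mathrm{Var} \approx \mu + \phi\mu^2$,
pooled within groups across all peaks), with per-peak estimates shrunk
toward the common value with weight `prior_df / (prior_df + df)`
(default prior_df = 10). This replaces a full empirical-Bayes tagwise
machinery with a defined, testable statistic; `edgeR::exactTest()` with
`rejection.region = "smallp"` agrees with the package's p-values at equal
libraries and serves as the cross-check in the tests.

A peak is a DAR when |log2FC| > 1 **strictly** and q < 0.05 **strictly**;
the fold change is `log2((mean_b + 0.125)/(mean_a + 0.125))` on normalized
means with a prior count of 0.125 to stabilize low-count peaks.

# Normalization and PCA

The log scale is `log2(count / size_factor + 1)` with median-of-ratios
size factors (geometric-mean reference restricted to features positive in
every sample). A regularized-log transform is intentionally *not*
re-implemented: the downstream statistics require only a
variance-stabilized log scale with library effects removed, and the simple
transform keeps every pipeline value reproducible by hand. Sample PCA is
`prcomp` on centered features; outlier screening is made quantitative
(distance from the population centroid in PC1–2 above 3 MADs) but only
flags — removal is a user decision, never automatic, because the original
screening criterion was visual.

# Peak-to-gene assignment and concordance

No mapping rule is stated for "genes containing a DAR", so the package
defines one and exposes it: a peak maps to every gene whose body
[start, end) or promoter window [TSS − w, TSS + w) overlaps it
(half-open; w defaults to 2000 bp; TSS is start for "+" genes and end for
"−" genes). All coordinates are 0-based half-open (BED convention)
end-to-end, with converters validating at the GRanges boundary.

For the expression-versus-accessibility scatter, each gene needs one
accessibility value; the package uses the fold change of the gene's most
significant tested peak (minimum q, ties by p then peak id), with a
maximum-|log2FC| alternative behind a flag, since the published figures do
not state their summarization. Concordance uses the strict rule: both
|log2FC| > 0.585 (= log2 1.5) with matching sign is concordant (up or
down), with opposite signs discordant, anything else below threshold.
Values landing exactly on 0.585 are below threshold — the boundary tests
pin this.

Gene-set over-representation is a one-sided hypergeometric tail
($p = P[X \ge k]$) against a user-supplied universe and GMT sets, BH
corrected across sets. This replaces a proprietary pathway algorithm with
the field-standard ORA; topology-aware methods are out of scope.

# Repertoire: clones, diversity, persistence

Clonal lineages are built from AIRR rearrangement records: sequences are
partitioned by V gene and J gene (alleles stripped, first gene of
ambiguous calls) and CDR3 length, then single-linkage clustered at
**≥ 70%** nucleotide junction identity (Hamming, lengths equal within a
partition). Single linkage and nucleotide identity are the defaults
because only the threshold is standard; complete linkage and amino-acid
identity are available as options. Clone ids are the lexicographically
smallest member sequence id, making output order-invariant and
bit-stable. Clone size defaults to the number of unique sequences, with
duplicate-count weighting behind a flag.

Diversity is reported as the Gini–Simpson index $1 - \sum p_i^2$. The
phrase "1 − the inverse Simpson's index" that sometimes labels such plots
is arithmetically problematic (the inverse Simpson index is ≥ 1, which
would make the quantity ≤ 0); the package interprets it as the
Gini–Simpson index — equivalently $1 - 1/D$ applied to the *Simpson
concentration* rather than its reciprocal — and emits all three variants
($\lambda$, $1-\lambda$, $1/\lambda$) so any convention can be recovered.

Persistence across timepoints requires clustering the **pooled** records
of both timepoints, so clone identity is established by the same
clustering that defines clones (not by post-hoc matching of two
partitions). Clone persistence is the fraction of first-timepoint clones
with members at the second timepoint; sequence persistence weights
second-timepoint sequences by duplicate count.

# Morphometry

Cell and nucleus areas are averaged over their five repeated measurements
*before* any ratio is formed; the cytoplasm area is the difference of
those means. The primary readout is the cytoplasm/nucleus ratio (the
inverted nucleus/cytoplasm variant is also returned, since the two
conventions appear in different places in this literature). Scalar
readouts are compared with the same mixed model as expression; per-cell
mitochondria counts use a Poisson log-linear model with likelihood-ratio
chi-square tests per group pair, BH corrected.

# The synthetic generators: what they emulate, and what not

`generate_multiomic()` draws NB counts with
$\mu = 2^{(\mathrm{baseline} + \alpha_{\mathrm{pop}} + b_{\mathrm{patient}})} \times \mathrm{lib}$:
per-feature baselines uniform on log2 [3, 9], patient effects
$N(0, 0.5^2)$ on the log2 scale, library factors log-uniform on
[0.5, 2] (so median-of-ratios normalization is actually exercised), and a
fraction `frac_de` (default 0.1) of features carrying a planted effect of
±2 log2 units concentrated in one target population. The default design
is the emulated study's: populations Pop2/Pop3 (blood) and
Pop A/B/D (BM) with 11 patients per compartment; dispersion defaults to
0.15. Where the source material states no value (effect-size distribution,
dispersion, library-size spread), the defaults are one-time choices of
realistic magnitudes for sorted-cell bulk assays, not estimates.

Peaks live on a one-chromosome toy genome with genes on a fixed stride
wide enough that a linked peak sits inside exactly one gene body and every
intergenic peak is farther than the promoter window from any gene. The
planted peak-to-gene map is therefore *provably* identical to
`assign_peaks_to_genes()` output — a self-consistency invariant the tests
assert peak by peak.

`generate_repertoire()` plants clones with Zipf-distributed sizes
(exponent 1.5), one unmutated founder sequence per observed clone, member
junctions carrying binomially many point mutations capped at 10% of the
junction length, and a configurable fraction of first-timepoint clones
reappearing at the second timepoint (fresh clones keep the timepoint's
clone count constant). Founders sharing a V/J/length partition are
rejection-sampled to differ at more than $\lfloor 0.3L \rfloor + 2\lfloor
0.1L\rfloor$ positions. This guard is deliberately stronger than "more
than 30% divergence": it guarantees that two maximally mutated members of
*different* clones can never reach 70% identity, so single-linkage
clustering recovers the planted partition exactly and persistence
estimates are noise-free by construction. Sequencing depth defaults to
1000 sequences per sample, a deliberate scale-down of bulk VDJ depth
(~300k) that preserves the clone-structure properties being tested.

Neither generator attempts read-level realism: no GC or length biases, no
peak-shape or fragment model, no somatic-hypermutation phylogenies, no
batch effects. Passing tests therefore demonstrate correctness of the
statistics under the stated model, not robustness to artifacts real data
may carry.

# Numerical choices and degenerate inputs

* REML optimization: `optimize()` over $\log\lambda \in [-14, 14]$,
  tolerance 1e-8, with the $\lambda = 0$ boundary compared explicitly and
  preferred on ties (this resolves the flat-likelihood case where patients
  are confounded with residuals).
* Constant features: zero variance components, all contrast p-values 1.
* Non-finite contrast SEs: p set to 1 with a warning.
* Exact test with all-zero totals: p = 1, fold change 0.
* All-zero peaks: dispersion 0, flagged.
* Ties in per-gene peak summarization and clone ranking are broken by id,
  never by input order.
* Every generator draws from a single `set.seed(config$seed)` stream, so
  equal configs give bit-identical output.

# Problem sizes used in validation

The bundled validation runs use 2000 genes × 40 samples for the null-FDR
study (5 populations, 8 patients per compartment), 2000 peaks × 12
samples with 200 planted effects for accessibility recovery, 200 clones ×
600 sequences per timepoint for persistence recovery, and 100 random
partitions of up to 50 sequences for the clustering oracle — sizes chosen
so the whole suite re-runs from scratch in minutes while leaving the
estimators enough data to hit their documented tolerances.

# Known limitations

* The containment-df Tukey–Kramer p-values are approximate for severely
  unbalanced random-effect structures (exact small-sample df methods are
  not implemented).
* The NB exact test treats within-group library-size variation through
  the group-sum approximation described above.
* The DEG fold-change floor is compared inclusively (≥), which differs
  from the strict DAR rule (>) only on the exact boundary.
* ORA assumes exchangeable genes; no gene-length or accessibility bias
  correction is applied.
* The repertoire model has no allelic inclusion, no insertions/deletions
  within junctions, and isotypes are drawn independently of clones.

# A worked example

```{r example, eval = FALSE}
sim <- generate_multiomic(multiomic_sim_config(
  n_genes = 500, n_peaks = 400, patients_per_compartment = 4, seed = 1
))
nm <- normalize_log2(filter_low_count(sim$rna_counts, 150))
de <- run_mixed_de(nm, sim$design)
degs <- call_degs(de)
dar <- call_dars(run_nb_dar(sim$atac_counts, sim$design))
map <- assign_peaks_to_genes(sim$peaks, sim$genes)
dags <- dags_from_dars(dar$per_comparison, map)
overlap_sets(degs$per_comparison[["PopD_vs_Pop3"]], dags[["PopD_vs_Pop3"]])
```
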