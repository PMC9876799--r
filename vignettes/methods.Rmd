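---
title: "Methods: allelic-status calling, marker scoring and the association battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic-status calling, marker scoring and the association battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b2mscan)
```

# The problem

MMR-deficient tumours that genomically inactivate *B2M* lose HLA class I
antigen presentation, yet largely retain clinical benefit from checkpoint
blockade — pointing at HLA-unrestricted effectors (Vδ1/Vδ3 γδ T cells,
KIR-expressing cells). Testing that association requires three
computations that this package implements and cross-checks: a somatic
allelic-status caller for the target gene, single-sample immune marker
scoring of bulk RNA, and a battery of exact and regression-based
association tests. A synthetic-cohort generator with explicit ground truth
closes the loop: every caller and test can be validated against what was
simulated.

# The allelic-status model

**Mutation copy number.** With tumour purity $p$, a diploid admixed
normal and the locus at total tumour copy number $C$, a clonal mutation on
$m$ copies has expected VAF $mp / (Cp + 2(1-p))$ (implemented as
`expected_vaf()`, used by the simulator). At $C = 2$ the denominator is 2,
so VAF $= mp/2$, and inverting gives the estimator
$\widehat{m} = \mathrm{round}(2\,\mathrm{VAF}/p)$. We round halves *away
from zero*: the convention is stated nowhere upstream, and the IEC 60559
banker's rounding of R's `round()` would make $\widehat{m}$
platform-lore-dependent at exact halves (e.g. VAF 0.25 at purity 1).

**LOH.** $\widehat{m} = 2$ at total CN 2 means every tumour read carries
the mutation — no wild-type copy remains. We generalize to
$\widehat{m} \ge C$ for gene total copy number $C$, and accept a
precomputed segment minor copy number of 0 as an independent LOH signal
(the upstream WGS pipelines emit it; we deliberately do not re-implement
purity/ploidy segmentation).

**Phasing.** A single spanning read carrying both alternates suffices for
cis; spanning reads carrying each alternate alone, and none carrying both,
give trans; no alt-bearing spanning read leaves the pair unphaseable.
Conflicting evidence resolves to cis with a warning — a double-alt read is
physical evidence, single-alt spanning reads are expected on the wild-type
haplotype anyway.

**Decision tree.** Only clonal (P(subclonal) ≤ 0.5, strict threshold)
non-synonymous mutations are classified; one such mutation makes the
sample *mutant*. Cis groups (connected components of the cis relation)
collapse to one representative — we take the max-Mut_CN member, a choice
the source material leaves open; taking the first would only matter when
cis mutations disagree in Mut_CN, where the max is the conservative
reading of "one of these mutations was considered". Then: any LOH ⇒
**biallelic**; otherwise a trans pair with representative Mut_CN sum ≥ C ⇒
**biallelic**; otherwise sum ≥ C with unphaseable pairs ⇒ **potentially
biallelic**; otherwise **not biallelic**. Samples with a single mutation
and no LOH are mapped to *not biallelic* (the three-subgroup definition
only covers multi-mutation samples; the mapping is recorded in each call's
evidence trail as the single-mutation path). A homozygous deletion
($C = 0$, no mutation needed) is reported mutant/biallelic. Every call
carries an ordered, human-readable evidence list of the rules that fired.

# Marker scoring and clustering

Scores are arithmetic means of $\log_2(\mathrm{RPM}+1)$ over a set's genes
present in the matrix — log base 2 and pseudo-count 1 as conventionally
written; a natural-log variant was rejected to keep effect sizes in log2
units. RPM uses supplied library sizes when present, else column sums (the
denominator is not pinned down upstream). Missing genes are dropped with a
warning rather than zero-filled, so sets degrade gracefully across
annotations; a fully absent set scores `NA`, never 0. The KIR set is built
by rule (prefix `KIR`, substring `DL` or `DS`, case-sensitive official
symbols); the NK set is reduced to *NCR1* + *KLRF1*, stripping XCL1/XCL2 —
the upstream text spells these "XLC1/XLC2" in one place, an apparent typo,
so both spellings are stripped; the "NK CD56dim cells" set is removed
outright (three of its four genes are KIRs, collinear with the full KIR
set); the cytotoxicity set is fixed to the six genes encoding cytotoxic
molecules. Base marker sets beyond these edits are supplied as a GMT file
(their authoritative membership lives in supplementary material we do not
vendor); `inst/extdata/example_marker_sets.gmt` is a small synthetic
illustration, not the published collection.

Clustering Z-scores each row with the *population* (divisor $n$) standard
deviation — the upstream stack's default, unlike R's `sd()` — and runs
Ward linkage on Euclidean distances (`hclust` method `ward.D2`, the
variance-minimization algorithm for unsquared Euclidean input). Cutting at
$k = 2$ labels the higher-mean cluster "high". Merge ties are vanishingly
rare on continuous scores; `hclust`'s internal order is deterministic for
a given input, which is what the reproducibility contract requires.

# The association battery

* `fisher_exact_2x2`: the two-sided p is the probability-mass definition —
  the sum over tables (fixed margins) with hypergeometric probability ≤
  that of the observed table (a $1+10^{-7}$ relative slack absorbs
  floating-point ties). This is the convention under which the printed
  benefit table yields p = 0.0038. Zero-margin tables return p = 1 with a
  warning. The odds ratio is the raw $ad/bc$ (Inf/0 on zero cells);
  a Haldane-corrected estimate is available behind a flag, never default.
* `wilcoxon_rank_sum`: exact by full enumeration of rank assignments when
  $n_x+n_y \le 20$ and tie-free (the exact null is undefined under ties);
  otherwise mid-ranks, tie-corrected variance and a continuity-corrected
  normal approximation.
* `logistic_cb` wraps binomial IRLS (`stats::glm`); perfect separation is
  detected from the warning, non-convergence, or fitted probabilities
  equal to the outcomes, and flags the result with a missing p-value
  rather than a meaningless Wald statistic.
* `lm_adjusted` refuses rank-deficient designs by name instead of silently
  dropping columns. Categorical covariates are dummy-coded against the
  lexicographically first level, for determinism across runs.
* `lmm_random_intercepts` fits REML random intercepts per grouping factor
  (`lme4`); REML is assumed since the upstream optimizer settings are
  unstated, and the choice is recorded in the result's `method` field.
  The fixed-effect p is the Wald normal approximation (no denominator
  degrees of freedom are defined for unbalanced mixed designs).
  Single-level factors are dropped; with none left the model degrades to
  OLS and provably equals it.
* `benjamini_hochberg`: standard step-up, capped at 1, NAs propagated.

# What the generator emulates — and what it does not

The generator draws, per sample: purity uniform on a configurable range
(default 0.3–0.9, matching WGS quality thresholds), near-diploid ploidy,
gene total copy number from weights over 1–4 (default mass 0.90 on 2:
no *B2M* copy-number gains/losses were observed among TCGA *B2M* mutants,
and MSI tumours are near-diploid; classes requiring ≥ 2 copies redraw
CN = 2), TMB lognormal (median 30 mutations/Mb, hypermutated), and a
clinical-benefit Bernoulli with logit
$0.2 + 2.4\,\mathrm{mut} + 0.01\,\mathrm{TMB}$ — arm-mean rates ≈ 62% /
95%, the printed cohort contrast. Mutant samples realize their assigned
truth class constructively (single-LOH or trans pair for biallelic,
unphaseable complementary pair for potentially biallelic, single
sub-threshold mutation or cis pair otherwise); read support is binomial at
the expected VAF with Poisson per-site depth (standard WGS noise model);
subclonal decoys multiply the expected VAF by a cancer-cell fraction of
0.3 and carry P(subclonal) > 0.5. Expression adds the configured log2
shifts (default +1.0 on TRDV1/TRDV3 and KIR genes — effect sizes are not
published on this scale; ±1 log2 unit is a testable, biologically modest
choice made once) plus N(0, 0.5) biological noise on the log2(RPM+1)
scale, then Poisson counts at lognormal library sizes (~20 M reads).

A green recovery test therefore establishes that the caller and scoring
invert *this* generative model — clean clonal structure, independent
genes, Poisson counts, no batch effects, no purity estimation error, no
mapping artefacts. It does not establish performance on real WGS/RNA-seq,
where purity and copy number are themselves estimates: the known
weak spot is the Mut_CN estimator's CN = 2 assumption, which biases the
copy-number sum test at CN 3–4 and high purity (the minor-CN LOH route is
immune). With the default CN weights this affects ~1–2% of mutant samples,
visible in the 95% (not 100%) recovery bound.

# Interfaces and formats

Tabular exchange is TSV; gene sets are GMT; trees are Newick (via `ape`);
reports and evidence are JSON. Configs are JSON rather than YAML: no YAML
parser is available in the offline dependency set, and JSON is loss-free
for these flat configs. Percentages in reports are printed integer-rounded
except below 10%, which keep one decimal — the convention of the clinical
tables these reports mirror, making printed-number comparisons exact
string comparisons.

# Known limitations

* No WGS/RNA primary analysis: purity, copy number, phasing counts and
  library sizes are inputs, not estimates.
* The caller assumes the Mut_CN formula's diploid-locus denominator (see
  above); supplying minor copy numbers restores robustness at CN ≠ 2.
* Differential expression (limma-voom class), survival analysis and any
  imaging/single-cell processing are out of scope.
* The mixed-model p-value is a Wald approximation; small-group inference
  should not lean on it.
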