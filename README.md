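# b2mscan

Mismatch-repair-deficient (MMR-d) tumours respond exceptionally well to
immune checkpoint blockade (ICB), a response classically attributed to
CD8+ T cells recognizing neoantigens on HLA class I. Yet many MMR-d tumours
inactivate β2-microglobulin (*B2M*), the obligate HLA class I subunit —
and, paradoxically, keep responding, apparently through HLA-unrestricted
effectors such as Vδ1/Vδ3 γδ T cells and KIR-expressing cells. `b2mscan`
packages the computational side of that analysis so it can be rerun,
audited and stress-tested on cohorts with known ground truth:

1. **Somatic allelic-status calling.** For a target gene (default *B2M*),
   each mutation's copy number is estimated as

   *Mut_CN = round(2 · VAF / purity)*

   (halves away from zero). A mutation with Mut_CN reaching the gene's
   total copy number — or a segment minor copy number of 0 — is consistent
   with loss of heterozygosity (LOH). Samples with multiple clonal
   non-synonymous mutations are phased from spanning reads (cis / trans /
   unphaseable) and classified **biallelic** (trans pair whose integer
   Mut_CN sum reaches the gene copy number, or any LOH),
   **potentially biallelic** (unphaseable, sum still reaches the copy
   number, no LOH) or **not biallelic** (sum falls short, no LOH); cis
   groups collapse to a single representative. Subclonal mutations
   (P(subclonal) > 0.5) and synonymous ones never move the call.
2. **Immune marker scoring.** Per-sample infiltration scores are the mean
   log2(RPM + 1) over marker gene sets, including rule-built sets: KIR
   (symbols starting `KIR` and containing `DL`/`DS`), γδ1/3 T cells
   (*TRDV1*, *TRDV3*), CD4, NK (*NCR1*, *KLRF1*) and cytotoxic molecules
   (*GZMA/B/H, PRF1, GNLY, CTSW*). Z-scored score matrices are clustered
   into high/low infiltration groups by Ward linkage on Euclidean distance.
3. **Association battery.** Fisher's exact test (probability-mass
   two-sided p), exact/approximate Wilcoxon rank-sum, logistic regression
   of clinical benefit (adjustable for TMB and tumour site), OLS and
   random-intercept mixed models for expression, Benjamini–Hochberg FDR.
4. **Synthetic cohorts.** A generator with explicit ground truth — binomial
   read sampling at the purity/copy-number expected VAF, spanning-read
   phasing evidence, expression shifts on TRDV/KIR genes, logistic
   clinical-benefit outcomes — so that every stage above is testable
   without access-controlled data.

## Worked example

```r
library(b2mscan)

co    <- simulate_cohort(simulation_config(n_samples = 120, seed = 7))
calls <- call_allelic_status_cohort(co$mutations, co$genomics, co$phasing)
table(calls$b2m_status, calls$biallelic_class)
#>            biallelic not_applicable not_biallelic potentially_biallelic
#>   mutant          22              0             9                    10
#>   wildtype         0             79             0                     0

sets <- assemble_default_sets(rownames(co$expression$counts))
sc   <- score_sets(co$expression$counts, sets, normalize = TRUE,
                   library_sizes = co$expression$library_sizes)
mut  <- calls$b2m_status == "mutant"
wilcoxon_rank_sum(sc["γδ1/3 T cells", mut], sc["γδ1/3 T cells", !mut])$p_value
#> 3.01e-16   # mutants score ~0.97 log2 units higher (simulated shift: 1.0)

xt <- crosstab_cb(calls, co$clinical)
xt$table; xt$rates
#>          CB NCB         mutant wildtype
#> mutant   36   5             88       71
#> wildtype 56  23
fisher_exact_2x2(xt$table)$p_value
#> 0.0424
```

The 41 mutant tumours have an 88% clinical-benefit rate versus 71% in
wildtype — the simulated analogue of the cohort-study contrast. On the
published cohort's printed counts (mutant 20 CB / 1 NCB, wildtype
31 CB / 19 NCB), `crosstab_cb` reports arm rates 95% and 62% and
`fisher_exact_2x2` gives p = 0.0038.

`run_pipeline(pipeline_config(...))` chains all stages and writes
calls/scores/clusters/associations plus a JSON report; a thin CLI lives at
`inst/cli/b2mscan` (subcommands `simulate`, `call-b2m`, `score-sets`,
`run-all`, JSON configs).

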