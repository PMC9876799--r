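test_that("mutation_copy_number rounds half away from zero and guards", {
  expect_identical(mutation_copy_number(0.5, 0.5), 2L)
  expect_identical(mutation_copy_number(0.25, 1.0), 1L)  # 0.5 -> 1
  expect_identical(mutation_copy_number(0.0, 0.8), 0L)
  expect_identical(mutation_copy_number(0.375, 0.5), 2L) # 1.5 -> 2
  expect_error(mutation_copy_number(0.5, 0), "purity")
  expect_warning(mutation_copy_number(0.9, 0.1), "underestimated")
})

test_that("mutation_copy_number is monotone in VAF at fixed purity", {
  for (purity in c(0.2, 0.5, 0.8, 1)) {
    vaf <- seq(0, 1, by = 0.01)
    mc <- suppressWarnings(mutation_copy_number(vaf, purity))
    expect_true(all(diff(mc) >= 0))
  }
})

test_that("call_loh follows the all-copies-mutated / lost-minor rules", {
  expect_true(call_loh(2, 2))
  expect_false(call_loh(1, 2))
  expect_true(call_loh(1, 1, gene_minor_cn = 0))
  expect_true(call_loh(1, 2, gene_minor_cn = 0))
  expect_false(call_loh(1, 3, gene_minor_cn = 1))
  expect_true(call_loh(3, 3))
})

test_that("phase_pair applies the spanning-read definitions", {
  obs <- function(both, a, b) list(spanning_reads_both_alt = both,
                                   spanning_reads_a_only = a,
                                   spanning_reads_b_only = b)
  expect_identical(phase_pair(obs(3, 0, 0)), "cis")
  expect_identical(phase_pair(obs(0, 4, 5)), "trans")
  expect_identical(phase_pair(obs(0, 0, 0)), "unphaseable")
  expect_identical(phase_pair(obs(0, 4, 0)), "unphaseable")
  expect_warning(r <- phase_pair(obs(1, 2, 0)), "conflicting")
  expect_identical(r, "cis")
  expect_error(phase_pair(obs(-1, 0, 0)), "negative")
})

test_that("is_subclonal uses a strict 0.5 threshold", {
  expect_true(is_subclonal(0.6))
  expect_false(is_subclonal(0.5))
  expect_false(is_subclonal(0))
  expect_error(is_subclonal(1.2), "fraction")
})

test_that("compute_tmb divides mutations by megabases", {
  expect_equal(compute_tmb(5960, 2980), 2.0)
  expect_equal(compute_tmb(0, 3000), 0.0)
  expect_error(compute_tmb(10, 0), "megabases")
})

test_that("classifier reproduces the spec's worked examples", {
  # two trans mutations, Mut_CN 1+1 vs gene CN 2, no LOH -> biallelic
  rel2 <- matrix("trans", 2, 2)
  call <- classify_allelic_status(fx_mutations(c(1, 1)), fx_genomics(2, 1),
                                  fx_phasing(rel2))
  expect_identical(call$b2m_status, "mutant")
  expect_identical(call$biallelic_class, "biallelic")

  # one mutation with Mut_CN 2 = gene CN -> LOH -> biallelic
  call <- classify_allelic_status(fx_mutations(2), fx_genomics(2, 1))
  expect_identical(call$biallelic_class, "biallelic")
  expect_true(call$loh_per_mutation[["m1"]])

  # two unphaseable mutations, sum reaches CN, no LOH -> potentially
  relU <- matrix("unphaseable", 2, 2)
  call <- classify_allelic_status(fx_mutations(c(1, 1)), fx_genomics(2, 1),
                                  fx_phasing(relU))
  expect_identical(call$biallelic_class, "potentially_biallelic")

  # two cis mutations collapse to one representative -> not biallelic
  relC <- matrix("cis", 2, 2)
  call <- classify_allelic_status(fx_mutations(c(1, 1)), fx_genomics(2, 1),
                                  fx_phasing(relC))
  expect_identical(call$biallelic_class, "not_biallelic")
  expect_match(paste(call$evidence, collapse = " "), "cis")
})

test_that("classifier handles wildtype, deletion, and error paths", {
  call <- classify_allelic_status(fx_mutations(integer(0)), fx_genomics(2, 1))
  expect_identical(call$b2m_status, "wildtype")
  expect_identical(call$biallelic_class, "not_applicable")

  # homozygous deletion counts as mutant/biallelic
  call <- classify_allelic_status(fx_mutations(integer(0)),
                                  fx_genomics(0L, 0L))
  expect_identical(call$b2m_status, "mutant")
  expect_identical(call$biallelic_class, "biallelic")

  expect_error(
    classify_allelic_status(fx_mutations(1, gene = "TP53"),
                            fx_genomics(2, 1)),
    "other than target")

  # missing phasing row defaults to unphaseable, with a warning
  expect_warning(
    call <- classify_allelic_status(fx_mutations(c(1, 1)),
                                    fx_genomics(2, 1), phasing = NULL),
    "unphaseable")
  expect_identical(call$biallelic_class, "potentially_biallelic")
})

test_that("every considered mutation appears in the Mut_CN map", {
  m <- fx_mutations(c(1, 1, 2), effect = c("non_synonymous", "synonymous",
                                           "non_synonymous"),
                    subp = c(0, 0, 0.9))
  call <- suppressWarnings(classify_allelic_status(m, fx_genomics(2, 1)))
  expect_setequal(names(call$mut_cn_per_mutation), m$mutation_id)
})

test_that("synonymous and subclonal mutations never change the call", {
  grid <- list(list(mc = c(1, 1), rel = "trans"),
               list(mc = c(1, 1), rel = "unphaseable"),
               list(mc = 2, rel = NULL),
               list(mc = 1, rel = NULL))
  for (g in grid) {
    n <- length(g$mc)
    ph <- if (n == 2) fx_phasing(matrix(g$rel, 2, 2)) else NULL
    base <- classify_allelic_status(fx_mutations(g$mc), fx_genomics(2, 1), ph)
    extra <- rbind(fx_mutations(g$mc),
                   fx_mutations(1, effect = "synonymous")[
                     , names(fx_mutations(1))],
                   fx_mutations(2, subp = 0.8))
    extra$mutation_id <- paste0("m", seq_len(nrow(extra)))
    with_decoys <- suppressWarnings(
      classify_allelic_status(extra, fx_genomics(2, 1), ph))
    expect_identical(with_decoys$b2m_status, base$b2m_status)
    expect_identical(with_decoys$biallelic_class, base$biallelic_class)
  }
})

test_that("classifier agrees with the rules oracle on a random subsample", {
  set.seed(123)
  grid <- fx_enumeration_grid(max_muts = 2)
  for (cfgi in sample(length(grid), 400)) {
    cfg <- grid[[cfgi]]
    n <- length(cfg$mut_cn)
    ph <- if (n >= 2) fx_phasing(cfg$rel) else NULL
    got <- suppressWarnings(classify_allelic_status(
      fx_mutations(cfg$mut_cn), fx_genomics(cfg$gene_cn, cfg$minor_cn), ph))
    want <- oracle_classify(cfg$mut_cn, cfg$rel, cfg$gene_cn, cfg$minor_cn)
    expect_identical(c(got$b2m_status, got$biallelic_class), want,
                     info = paste("config", cfgi))
  }
})

test_that("cohort-level calling joins mutations, genomics and phasing", {
  co <- simulate_cohort(simulation_config(n_samples = 50, seed = 21))
  calls <- suppressWarnings(
    call_allelic_status_cohort(co$mutations, co$genomics, co$phasing))
  expect_identical(calls$sample_id, co$genomics$sample_id)
  expect_true(all(calls$biallelic_class[calls$b2m_status == "wildtype"] ==
                    "not_applicable"))
  expect_length(attr(calls, "calls"), nrow(co$genomics))
})
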