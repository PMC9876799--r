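#' Simulation configuration for a synthetic ICB cohort
#'
#' Describes the generative model of [simulate_cohort()]: a cohort of
#' mismatch-repair-deficient tumours in which a fraction carries somatic
#' mutations of a target gene (B2M by default), mutant tumours shift the
#' expression of the TRDV1/TRDV3 (gamma-delta T cell) and KIR marker genes,
#' and clinical benefit of checkpoint blockade follows a logistic model in
#' mutation status and tumour mutational burden.
#'
#' Defaults encode the cohort structure reported for MMR-d tumours treated
#' with PD-1 blockade: ~30% of samples mutant, ~62% of mutants biallelic,
#' near-diploid gene copy number (no B2M copy-number gains/losses were seen
#' among TCGA B2M mutants, hence the mass at CN 2), WGS-like depth ~100x,
#' hypermutated TMB (lognormal around 30 mutations/Mb), and logistic
#' coefficients whose arm-mean benefit rates are ~62% (wildtype) and ~95%
#' (mutant).
#'
#' @param n_samples number of tumours (>= 2).
#' @param frac_b2m_mut fraction of samples carrying target-gene mutations.
#' @param frac_biallelic_given_mut,frac_potentially_given_mut fractions of
#'   mutant samples with truly biallelic / potentially-biallelic inactivation
#'   (the remainder is not biallelic).
#' @param purity_range tumour purity is drawn uniformly on this interval.
#' @param depth mean sequencing depth; per-site depth is Poisson(depth).
#' @param gene_cn_weights sampling weights for gene total copy number 1..4.
#' @param effect_trdv,effect_kir log2-unit expression shift added to
#'   TRDV1/TRDV3 and KIR genes in mutant samples.
#' @param cb_intercept,cb_beta_b2m,cb_beta_tmb logistic coefficients for the
#'   clinical-benefit outcome (linear predictor
#'   \code{cb_intercept + cb_beta_b2m * mutant + cb_beta_tmb * TMB}).
#' @param tmb_meanlog,tmb_sdlog lognormal parameters of TMB (mutations/Mb).
#' @param mean_library_size,library_size_sdlog RNA-seq library size model.
#' @param expr_bio_sd per-sample biological noise, sd on the log2(RPM+1) scale.
#' @param gene target gene symbol.
#' @param seed integer RNG seed.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples = 200L,
                              frac_b2m_mut = 0.30,
                              frac_biallelic_given_mut = 0.62,
                              frac_potentially_given_mut = 0.19,
                              purity_range = c(0.3, 0.9),
                              depth = 100,
                              gene_cn_weights = c(0.05, 0.90, 0.04, 0.01),
                              effect_trdv = 1.0,
                              effect_kir = 1.0,
                              cb_intercept = 0.2,
                              cb_beta_b2m = 2.4,
                              cb_beta_tmb = 0.01,
                              tmb_meanlog = log(30),
                              tmb_sdlog = 0.5,
                              mean_library_size = 2e7,
                              library_size_sdlog = 0.3,
                              expr_bio_sd = 0.5,
                              gene = "B2M",
                              seed = 1L) {
  if (n_samples < 2) stop_("'n_samples' must be >= 2")
  if (depth < 1) stop_("'depth' must be >= 1")
  assert_fraction(frac_b2m_mut, "frac_b2m_mut")
  assert_fraction(frac_biallelic_given_mut, "frac_biallelic_given_mut")
  assert_fraction(frac_potentially_given_mut, "frac_potentially_given_mut")
  if (frac_biallelic_given_mut + frac_potentially_given_mut > 1)
    stop_("biallelic + potentially-biallelic fractions exceed 1")
  assert_fraction(purity_range, "purity_range", allow_zero = FALSE)
  if (length(purity_range) != 2 || purity_range[1] > purity_range[2])
    stop_("'purity_range' must be an increasing pair of fractions")
  if (length(gene_cn_weights) != 4 || any(gene_cn_weights < 0) ||
      sum(gene_cn_weights) <= 0)
    stop_("'gene_cn_weights' must be 4 non-negative weights for CN 1..4")
  cfg <- list(n_samples = as.integer(n_samples), frac_b2m_mut = frac_b2m_mut,
              frac_biallelic_given_mut = frac_biallelic_given_mut,
              frac_potentially_given_mut = frac_potentially_given_mut,
              purity_range = purity_range, depth = depth,
              gene_cn_weights = gene_cn_weights / sum(gene_cn_weights),
              effect_trdv = effect_trdv, effect_kir = effect_kir,
              cb_intercept = cb_intercept, cb_beta_b2m = cb_beta_b2m,
              cb_beta_tmb = cb_beta_tmb,
              tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
              mean_library_size = mean_library_size,
              library_size_sdlog = library_size_sdlog,
              expr_bio_sd = expr_bio_sd, gene = gene, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Expected variant allele frequency of a somatic mutation
#'
#' In a tumour of purity \eqn{p} whose tumour cells carry \code{total_cn}
#' copies of the locus, \code{mut_cn} of them mutated, and whose admixed
#' normal cells are diploid wild type, the expected VAF is
#' \deqn{\frac{m p}{C p + 2 (1 - p)}.}
#' At \code{total_cn = 2} this is the inverse of the mutation copy number
#' estimator \code{round(2 VAF / purity)} used by [mutation_copy_number()].
#'
#' @param mut_cn mutated copies (integer, \code{1 <= mut_cn <= total_cn};
#'   0 allowed and yields 0).
#' @param total_cn total tumour copies at the locus (>= 1).
#' @param purity tumour cell fraction in (0, 1].
#' @return expected VAF in [0, 1].
#' @examples
#' expected_vaf(2, 2, 0.5)  # 0.5
#' expected_vaf(1, 2, 1.0)  # 0.5
#' @export
expected_vaf <- function(mut_cn, total_cn, purity) {
  assert_fraction(purity, "purity", allow_zero = FALSE)
  if (any(mut_cn < 0) || any(total_cn < 1)) stop_("invalid copy numbers")
  if (any(mut_cn > total_cn))
    stop_("invalid configuration: mut_cn exceeds total_cn")
  mut_cn * purity / (total_cn * purity + 2 * (1 - purity))
}

#' Simulate spanning-read phasing evidence for a mutation pair
#'
#' Mimics what manual inspection of reads spanning two nearby somatic
#' mutations yields: for a \emph{cis} pair at least one spanning read carries
#' both alternate alleles; for a \emph{trans} pair spanning reads carry
#' exactly one alternate each; for an \emph{unphaseable} pair (loci too
#' distant for any read) there are no spanning reads at all, and a trans/cis
#' request at zero depth degrades to unphaseable.
#'
#' @param relation one of "cis", "trans", "unphaseable".
#' @param depth mean read depth at the locus (>= 0).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a one-row data.frame with columns \code{spanning_reads_both_alt},
#'   \code{spanning_reads_a_only}, \code{spanning_reads_b_only},
#'   \code{spanning_reads_neither} and \code{relation} (the realized one).
#' @export
simulate_phasing_reads <- function(relation, depth, seed = 1L) {
  relation <- match.arg(relation, c("cis", "trans", "unphaseable"))
  if (depth < 0) stop_("'depth' must be >= 0")
  with_seed(seed, {
    out <- data.frame(spanning_reads_both_alt = 0L, spanning_reads_a_only = 0L,
                      spanning_reads_b_only = 0L, spanning_reads_neither = 0L,
                      relation = "unphaseable", stringsAsFactors = FALSE)
    if (relation == "unphaseable" || depth == 0) return(out)
    # ~30% of reads at a site span both loci of a nearby pair
    span <- max(1L, stats::rpois(1, 0.3 * depth))
    if (relation == "cis") {
      both <- max(1L, stats::rbinom(1, span, 0.45))
      out$spanning_reads_both_alt <- both
      out$spanning_reads_neither <- span - both
    } else {
      a <- max(1L, stats::rbinom(1, span, 0.3))
      b <- max(1L, stats::rbinom(1, max(span - a, 1L), 0.4))
      out$spanning_reads_a_only <- a
      out$spanning_reads_b_only <- min(b, span - a)
      if (out$spanning_reads_b_only < 1L) { # force trans evidence
        out$spanning_reads_a_only <- a - 1L
        out$spanning_reads_b_only <- 1L
      }
      out$spanning_reads_neither <- span - out$spanning_reads_a_only -
        out$spanning_reads_b_only
    }
    out$relation <- relation
    out
  })
}

# Marker gene panel used by the generator: fixed baseline log2(RPM+1).
sim_gene_panel <- function() {
  kir <- c(KIR2DL1 = 1.0, KIR2DL3 = 1.2, KIR2DL4 = 1.5, KIR3DL1 = 1.1,
           KIR3DL2 = 1.3, KIR3DL3 = 0.8, KIR2DS4 = 1.0)
  imm <- c(TRDV1 = 2.0, TRDV3 = 1.3, CD4 = 5.0, NCR1 = 2.0, KLRF1 = 2.3,
           GZMA = 5.5, GZMB = 5.0, GZMH = 4.5, PRF1 = 5.2, GNLY = 5.8,
           CTSW = 4.8, B2M = 9.0)
  bg <- stats::setNames(seq(3, 8, length.out = 25),
                        sprintf("BKG%03d", seq_len(25)))
  c(imm, kir, bg)
}

# Construct the mutation set realizing a ground-truth biallelic class at a
# given gene CN. Returns list(mut_cn, relation, minor_cn); relation is the
# pairwise relation when two mutations are produced.
sim_mutation_plan <- function(class, gene_cn) {
  if (class == "biallelic") {
    if (gene_cn == 1L || stats::runif(1) < 0.5)
      return(list(mut_cn = gene_cn, relation = NULL, minor_cn = 0L))
    a <- sample.int(gene_cn - 1L, 1L)
    return(list(mut_cn = c(a, gene_cn - a), relation = "trans", minor_cn = 1L))
  }
  if (class == "potentially_biallelic")
    return(list(mut_cn = c(1L, gene_cn - 1L), relation = "unphaseable",
                minor_cn = 1L))
  if (stats::runif(1) < 0.5)  # not_biallelic
    return(list(mut_cn = 1L, relation = NULL, minor_cn = 1L))
  list(mut_cn = c(1L, 1L), relation = "cis", minor_cn = 1L)
}

#' Simulate a ground-truth-labelled cohort
#'
#' Draws a full synthetic cohort: per-sample purity, ploidy and gene copy
#' number; somatic mutations of the target gene with binomial read sampling
#' at the purity/copy-number expected VAF (Poisson per-site depth);
#' spanning-read phasing observations; a raw-count expression matrix whose
#' TRDV1/TRDV3 and KIR genes are shifted in mutant samples; and clinical
#' benefit outcomes from the configured logistic model. Synonymous and
#' subclonal decoy mutations are sprinkled in so that caller invariance to
#' them is exercised.
#'
#' @param config a [simulation_config()].
#' @return an object of class \code{synthetic_cohort}: a list with elements
#'   \code{mutations}, \code{genomics}, \code{phasing}, \code{clinical},
#'   \code{truth} (data.frames), \code{expression} (list with \code{counts}
#'   matrix genes x samples and \code{library_sizes}) and \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$frac_b2m_mut > 0 && cfg$n_samples * cfg$frac_b2m_mut < 1)
    warn_("degenerate config: expected number of mutant samples < 1")
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    purity <- stats::runif(n, cfg$purity_range[1], cfg$purity_range[2])
    ploidy <- round(stats::rnorm(n, 2, 0.1), 2)
    gene_cn <- sample.int(4L, n, replace = TRUE, prob = cfg$gene_cn_weights)
    mb <- round(stats::runif(n, 2700, 2900), 1)
    is_mut <- stats::runif(n) < cfg$frac_b2m_mut
    cls_probs <- c(biallelic = cfg$frac_biallelic_given_mut,
                   potentially_biallelic = cfg$frac_potentially_given_mut,
                   not_biallelic = 1 - cfg$frac_biallelic_given_mut -
                     cfg$frac_potentially_given_mut)
    truth_class <- rep("not_applicable", n)
    truth_class[is_mut] <- sample(names(cls_probs), sum(is_mut),
                                  replace = TRUE, prob = cls_probs)
    # classes other than biallelic require >= 2 gene copies to be realizable
    fix <- is_mut & truth_class != "biallelic" & gene_cn < 2L
    gene_cn[fix] <- 2L
    minor_cn <- ifelse(gene_cn >= 2L, 1L, 0L)

    mut_rows <- list(); phase_rows <- list(); midx <- 0L
    b2m_locus <- c(44711477L, 44718877L)  # chr15 B2M gene body
    new_mut <- function(sample, mut_cn, eff, subp, cn, pur, ccf = 1) {
      midx <<- midx + 1L
      dp <- max(1L, stats::rpois(1, cfg$depth))
      ev <- min(expected_vaf(mut_cn, cn, pur) * ccf, 1)
      alt <- stats::rbinom(1, dp, ev)
      data.frame(sample_id = sample, mutation_id = sprintf("M%05d", midx),
                 gene = cfg$gene, chrom = "15",
                 pos = sample(seq(b2m_locus[1], b2m_locus[2]), 1),
                 ref = sample(c("A", "C", "G", "T"), 1), alt_allele = "T",
                 vaf = alt / dp, alt_reads = alt, ref_reads = dp - alt,
                 effect = eff, subclonal_probability = subp,
                 true_mut_cn = mut_cn, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n)) {
      sid <- ids[i]
      core_ids <- character(0)
      if (is_mut[i]) {
        plan <- sim_mutation_plan(truth_class[i], gene_cn[i])
        minor_cn[i] <- plan$minor_cn
        for (m in plan$mut_cn) {
          row <- new_mut(sid, m, "non_synonymous", 0, gene_cn[i], purity[i])
          mut_rows[[length(mut_rows) + 1L]] <- row
          core_ids <- c(core_ids, row$mutation_id)
        }
        if (length(core_ids) == 2L) {
          obs <- simulate_phasing_reads(plan$relation, cfg$depth,
                                        seed = cfg$seed + 7L * midx)
          phase_rows[[length(phase_rows) + 1L]] <-
            cbind(data.frame(sample_id = sid, mutation_id_a = core_ids[1],
                             mutation_id_b = core_ids[2],
                             stringsAsFactors = FALSE),
                  obs[, 1:4])
        }
      }
      # decoys: synonymous and subclonal hits must never move the call
      if (stats::runif(1) < 0.25)
        mut_rows[[length(mut_rows) + 1L]] <-
          new_mut(sid, 1L, "synonymous", 0, gene_cn[i], purity[i])
      if (stats::runif(1) < 0.15)
        mut_rows[[length(mut_rows) + 1L]] <-
          new_mut(sid, 1L, "non_synonymous", stats::runif(1, 0.6, 0.95),
                  gene_cn[i], purity[i], ccf = 0.3)
    }
    mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
      data.frame(sample_id = character(0), mutation_id = character(0),
                 gene = character(0), chrom = character(0), pos = integer(0),
                 ref = character(0), alt_allele = character(0),
                 vaf = numeric(0), alt_reads = integer(0),
                 ref_reads = integer(0), effect = character(0),
                 subclonal_probability = numeric(0), true_mut_cn = integer(0))
    phasing <- if (length(phase_rows)) do.call(rbind, phase_rows) else
      data.frame(sample_id = character(0), mutation_id_a = character(0),
                 mutation_id_b = character(0),
                 spanning_reads_both_alt = integer(0),
                 spanning_reads_a_only = integer(0),
                 spanning_reads_b_only = integer(0),
                 spanning_reads_neither = integer(0))

    genomics <- data.frame(sample_id = ids, purity = purity, ploidy = ploidy,
                           gene_total_cn = gene_cn, gene_minor_cn = minor_cn,
                           megabases_sequenced = mb, stringsAsFactors = FALSE)

    # expression: baseline log2(RPM+1) + status shifts + biological noise
    base <- sim_gene_panel()
    genes <- names(base)
    shift <- matrix(0, length(genes), n, dimnames = list(genes, ids))
    kir_genes <- grepl("^KIR", genes) & grepl("DL|DS", genes)
    shift[c("TRDV1", "TRDV3"), is_mut] <- cfg$effect_trdv
    shift[kir_genes, is_mut] <- cfg$effect_kir
    shift["B2M", is_mut] <- -1  # mutants lose B2M transcript
    x <- base + shift + matrix(stats::rnorm(length(genes) * n, 0,
                                            cfg$expr_bio_sd),
                               length(genes), n)
    rpm_true <- pmax(2^pmax(x, 0) - 1, 0)
    lib <- round(stats::rlnorm(n, log(cfg$mean_library_size),
                               cfg$library_size_sdlog))
    counts <- matrix(stats::rpois(length(rpm_true),
                                  t(t(rpm_true) * lib / 1e6)),
                     length(genes), n, dimnames = list(genes, ids))

    tmb <- stats::rlnorm(n, cfg$tmb_meanlog, cfg$tmb_sdlog)
    lp <- cfg$cb_intercept + cfg$cb_beta_b2m * is_mut + cfg$cb_beta_tmb * tmb
    cb <- stats::rbinom(n, 1, stats::plogis(lp))
    tumour_type <- sample(c("colorectal", "stomach", "endometrium", "other"),
                          n, replace = TRUE, prob = c(.45, .15, .2, .2))
    biopsy_site <- sample(c("primary", "liver", "lymph_node", "peritoneum",
                            "lung"), n, replace = TRUE,
                          prob = c(.3, .3, .2, .1, .1))
    response <- ifelse(cb == 1,
                       sample(c("CR", "PR", "SD"), n, replace = TRUE,
                              prob = c(.15, .55, .3)), "PD")
    clinical <- data.frame(sample_id = ids, tumour_type = tumour_type,
                           biopsy_site = biopsy_site,
                           clinical_benefit = ifelse(cb == 1, "CB", "NCB"),
                           response = response, tmb = tmb,
                           stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = ids,
                        b2m_status = ifelse(is_mut, "mutant", "wildtype"),
                        biallelic_class = truth_class,
                        stringsAsFactors = FALSE)
    out <- list(mutations = mutations, genomics = genomics, phasing = phasing,
                expression = list(counts = counts, library_sizes =
                                    stats::setNames(lib, ids)),
                clinical = clinical, truth = truth, config = cfg)
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$config$n_samples, "samples,",
      sum(x$truth$b2m_status == "mutant"), "mutant;",
      nrow(x$mutations), "mutations,", nrow(x$expression$counts),
      "genes\n")
  invisible(x)
}

#' Write a synthetic cohort as the standard pipeline input files
#'
#' Emits \code{mutations.tsv}, \code{genomics.tsv}, \code{phasing.tsv},
#' \code{expression.tsv} (genes x samples raw counts with a leading
#' \code{gene} column), \code{library_sizes.tsv}, \code{clinical.tsv},
#' \code{truth.tsv} and \code{config.json}.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(cohort$genomics, file.path(dir, "genomics.tsv"))
  write_tsv(cohort$phasing, file.path(dir, "phasing.tsv"))
  expr <- data.frame(gene = rownames(cohort$expression$counts),
                     cohort$expression$counts, check.names = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(data.frame(sample_id = names(cohort$expression$library_sizes),
                       library_size = unname(cohort$expression$library_sizes)),
            file.path(dir, "library_sizes.tsv"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
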