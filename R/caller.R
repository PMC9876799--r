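#' Estimate a mutation's copy number from VAF and purity
#'
#' For a tumour locus at total copy number 2 with a diploid admixed normal,
#' the number of tumour copies carrying a somatic mutation is estimated as
#' \code{round(2 * VAF / purity)}, rounded to an integer with halves rounded
#' away from zero.
#'
#' @param vaf variant allele frequency in [0, 1] (vectorized).
#' @param purity tumour cell fraction in (0, 1].
#' @return integer vector of estimated mutated copies (>= 0). Values above
#'   10 trigger a warning (implausible; usually a purity underestimate).
#' @examples
#' mutation_copy_number(0.5, 0.5)   # 2
#' mutation_copy_number(0.25, 1.0)  # 1 (0.5 rounds away from zero)
#' @export
mutation_copy_number <- function(vaf, purity) {
  assert_fraction(vaf, "vaf")
  if (any(!is.finite(purity) | purity <= 0 | purity > 1))
    stop_("'purity' must be in (0, 1]")
  mc <- as.integer(round_half_away(2 * vaf / purity))
  if (any(mc > 10L))
    warn_("mutation copy number > 10: purity is likely underestimated")
  mc
}

#' Is a mutation consistent with loss of heterozygosity?
#'
#' A mutation shows LOH when no wild-type copy of the locus remains in the
#' tumour cells: its estimated copy number reaches the gene's total copy
#' number (at total CN 2, Mut_CN = 2 is the classic signature), or the
#' segment's minor allele copy number is 0 when segment data are available.
#'
#' @param mut_cn estimated mutated copies (from [mutation_copy_number()]).
#' @param gene_total_cn total tumour copies of the gene (>= 1).
#' @param gene_minor_cn minor allele copy number, or \code{NA} when unknown.
#' @return logical (vectorized).
#' @export
call_loh <- function(mut_cn, gene_total_cn, gene_minor_cn = NA) {
  if (any(mut_cn < 0) || any(gene_total_cn < 1)) stop_("invalid copy numbers")
  mut_cn >= gene_total_cn | (!is.na(gene_minor_cn) & gene_minor_cn == 0)
}

#' Phase a mutation pair from spanning-read counts
#'
#' A pair is \emph{cis} as soon as a single spanning read carries both
#' alternate alleles; \emph{trans} when no read carries both but each
#' alternate is seen alone on spanning reads; \emph{unphaseable} when no
#' spanning read carries any alternate (loci too distant, or no evidence).
#' Conflicting evidence (double-alt reads alongside single-alt reads)
#' resolves to cis with a warning.
#'
#' @param obs a list or one-row data.frame with counts
#'   \code{spanning_reads_both_alt}, \code{spanning_reads_a_only},
#'   \code{spanning_reads_b_only} (and optionally
#'   \code{spanning_reads_neither}).
#' @return "cis", "trans" or "unphaseable".
#' @export
phase_pair <- function(obs) {
  both <- obs$spanning_reads_both_alt
  a <- obs$spanning_reads_a_only
  b <- obs$spanning_reads_b_only
  if (any(c(both, a, b) < 0)) stop_("negative read counts")
  if (both >= 1) {
    if (a >= 1 || b >= 1)
      warn_("conflicting phasing evidence (double- and single-alt spanning reads); resolving to cis")
    return("cis")
  }
  if (a >= 1 && b >= 1) return("trans")
  "unphaseable"
}

#' Is a mutation subclonal?
#'
#' @param subclonal_probability probability in [0, 1].
#' @return \code{TRUE} iff the probability is strictly greater than 0.5,
#'   i.e. the mutation is more likely subclonal than clonal.
#' @export
is_subclonal <- function(subclonal_probability) {
  assert_fraction(subclonal_probability, "subclonal_probability")
  subclonal_probability > 0.5
}

#' Tumour mutational burden
#'
#' Genome-wide mutation count (SNVs, MNVs and indels) divided by the number
#' of megabases sequenced.
#'
#' @param n_mutations mutation count (>= 0).
#' @param megabases_sequenced megabases sequenced (> 0).
#' @return mutations per megabase.
#' @export
compute_tmb <- function(n_mutations, megabases_sequenced) {
  if (any(n_mutations < 0)) stop_("'n_mutations' must be >= 0")
  if (any(megabases_sequenced <= 0))
    stop_("'megabases_sequenced' must be > 0")
  n_mutations / megabases_sequenced
}

# connected components of the cis graph over mutation ids
cis_components <- function(ids, rel) {
  comp <- stats::setNames(seq_along(ids), ids)
  if (length(ids) > 1) {
    pairs <- names(rel)[rel == "cis"]
    for (p in pairs) {
      ab <- strsplit(p, "|", fixed = TRUE)[[1]]
      ca <- comp[ab[1]]; cb <- comp[ab[2]]
      if (ca != cb) comp[comp == cb] <- ca
    }
  }
  comp
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Classify the allelic status of a sample's target-gene mutations
#'
#' Implements the biallelic-inactivation decision tree for a single sample.
#' Only clonal (subclonal probability <= 0.5), non-synonymous mutations
#' enter the classifier; a sample is \code{mutant} as soon as one such
#' mutation exists (or the gene is homozygously deleted). Mutation copy
#' numbers come from \code{round(2 VAF / purity)}; LOH from [call_loh()].
#' With multiple mutations, cis groups (connected components of the cis
#' relation) collapse to their highest-Mut_CN representative, then:
#' \itemize{
#'   \item \strong{biallelic} if any mutation shows LOH, or some pair of
#'     representatives is in trans and the integer sum of representative
#'     Mut_CNs reaches the gene's integer copy number;
#'   \item \strong{potentially_biallelic} if no LOH and no trans evidence
#'     but the representative Mut_CN sum still reaches the gene copy number
#'     (pairs too distant to be phased);
#'   \item \strong{not_biallelic} if the sum falls short and no LOH.
#' }
#' A single clonal non-synonymous mutation is biallelic iff it shows LOH.
#'
#' @param mutations data.frame of this sample's mutations with columns
#'   \code{mutation_id}, \code{gene}, \code{vaf}, \code{effect}
#'   ("synonymous"/"non_synonymous") and optional
#'   \code{subclonal_probability} (default 0).
#' @param genomics one-row data.frame (or list) with \code{sample_id},
#'   \code{purity}, \code{gene_total_cn} and optional \code{gene_minor_cn}.
#' @param phasing optional data.frame of spanning-read observations with
#'   \code{mutation_id_a}, \code{mutation_id_b} and the count columns of
#'   [phase_pair()]. Missing pairs default to unphaseable with a warning.
#' @param gene target gene symbol; rows naming another gene are an error.
#' @return an object of class \code{allelic_status_call}: list with
#'   \code{sample_id}, \code{b2m_status}, \code{biallelic_class},
#'   \code{mut_cn_per_mutation}, \code{loh_per_mutation},
#'   \code{phasing_relations}, \code{clonal_nonsynonymous_count} and an
#'   ordered \code{evidence} character vector of fired rules.
#' @export
classify_allelic_status <- function(mutations, genomics, phasing = NULL,
                                    gene = "B2M") {
  g <- as.list(genomics)
  ev <- character(0)
  note <- function(msg) ev <<- c(ev, msg)
  res <- function(status, class) {
    out <- list(sample_id = g$sample_id %||% NA_character_,
                b2m_status = status, biallelic_class = class,
                mut_cn_per_mutation = mut_cn_map,
                loh_per_mutation = loh_map,
                phasing_relations = rel,
                clonal_nonsynonymous_count = n_clonal,
                evidence = ev)
    class(out) <- "allelic_status_call"
    out
  }
  mut_cn_map <- integer(0); loh_map <- logical(0)
  rel <- character(0); n_clonal <- 0L

  if (!is.null(mutations) && nrow(mutations) > 0) {
    if (any(mutations$gene != gene))
      stop_("mutation table contains gene(s) other than target '", gene, "'")
    mut_cn_map <- stats::setNames(
      mutation_copy_number(mutations$vaf, g$purity), mutations$mutation_id)
    if (g$gene_total_cn >= 1)
      loh_map <- stats::setNames(
        call_loh(mut_cn_map, g$gene_total_cn,
                 g$gene_minor_cn %||% NA), mutations$mutation_id)
    else
      loh_map <- stats::setNames(rep(NA, nrow(mutations)),
                                 mutations$mutation_id)
  }

  if ((g$gene_total_cn %||% 2L) == 0L) {
    note("homozygous deletion of the target gene: mutant, biallelic")
    return(res("mutant", "biallelic"))
  }

  if (is.null(mutations) || nrow(mutations) == 0) {
    note("no somatic mutations in target gene")
    return(res("wildtype", "not_applicable"))
  }

  subp <- mutations$subclonal_probability %||% rep(0, nrow(mutations))
  subp[is.na(subp)] <- 0
  clonal <- !is_subclonal(subp)
  nonsyn <- mutations$effect == "non_synonymous"
  if (any(!nonsyn))
    note(sprintf("%d synonymous mutation(s) excluded from classification",
                 sum(!nonsyn)))
  if (any(nonsyn & !clonal))
    note(sprintf("%d subclonal non-synonymous mutation(s) excluded (P(subclonal) > 0.5)",
                 sum(nonsyn & !clonal)))
  keep <- clonal & nonsyn
  n_clonal <- sum(keep)
  if (n_clonal == 0L) {
    note("no clonal non-synonymous mutation: wildtype")
    return(res("wildtype", "not_applicable"))
  }
  ids <- mutations$mutation_id[keep]
  mc <- mut_cn_map[ids]
  loh <- loh_map[ids]
  note(sprintf("%d clonal non-synonymous mutation(s): mutant", n_clonal))

  if (n_clonal == 1L) {
    if (loh[1]) {
      note(sprintf("single-mutation path: Mut_CN %d >= gene CN %d or minor CN 0 (LOH): biallelic",
                   mc[1], g$gene_total_cn))
      return(res("mutant", "biallelic"))
    }
    note("single-mutation path: no LOH: not_biallelic")
    return(res("mutant", "not_biallelic"))
  }

  # pairwise relations among clonal non-synonymous mutations
  rel <- character(0)
  for (i in seq_len(n_clonal - 1L)) for (j in seq((i + 1L), n_clonal)) {
    key <- pair_key(ids[i], ids[j])
    r <- NULL
    if (!is.null(phasing) && nrow(phasing) > 0) {
      hit <- which(pair_key(phasing$mutation_id_a,
                            phasing$mutation_id_b) == key)
      if (length(hit)) r <- phase_pair(phasing[hit[1L], ])
    }
    if (is.null(r)) {
      warn_("no phasing observation for pair ", key,
            "; defaulting to unphaseable")
      r <- "unphaseable"
    }
    rel[key] <- r
  }

  comp <- cis_components(ids, rel)
  reps <- vapply(split(ids, comp), function(grp) {
    grp[which.max(mc[grp])]  # cis group representative: max Mut_CN member
  }, character(1))
  if (length(reps) < n_clonal)
    note(sprintf("collapsed %d cis mutation(s) into group representative(s)",
                 n_clonal - length(reps)))
  cn_sum <- sum(mc[reps])
  has_trans <- FALSE
  if (length(reps) > 1) {
    grp_of <- comp[ids]
    for (key in names(rel)) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (grp_of[ab[1]] != grp_of[ab[2]] && rel[key] == "trans")
        has_trans <- TRUE
    }
  }

  if (any(loh)) {
    note("rule 1b: at least one mutation shows LOH: biallelic")
    return(res("mutant", "biallelic"))
  }
  if (length(reps) > 1 && has_trans && cn_sum >= g$gene_total_cn) {
    note(sprintf("rule 1a: mutations in trans and Mut_CN sum %d >= gene CN %d: biallelic",
                 cn_sum, g$gene_total_cn))
    return(res("mutant", "biallelic"))
  }
  if (length(reps) > 1 && !has_trans && cn_sum >= g$gene_total_cn) {
    note(sprintf("rule 2: pair(s) unphaseable, Mut_CN sum %d >= gene CN %d, no LOH: potentially_biallelic",
                 cn_sum, g$gene_total_cn))
    return(res("mutant", "potentially_biallelic"))
  }
  note(sprintf("rule 3: Mut_CN sum %d < gene CN %d and no LOH: not_biallelic",
               cn_sum, g$gene_total_cn))
  res("mutant", "not_biallelic")
}

#' @export
print.allelic_status_call <- function(x, ...) {
  cat(sprintf("<%s> %s / %s (%d clonal non-synonymous mutation(s))\n",
              x$sample_id, x$b2m_status, x$biallelic_class,
              x$clonal_nonsynonymous_count))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Call allelic status for every sample of a cohort
#'
#' Applies [classify_allelic_status()] per sample of a genomics table,
#' pairing each sample with its mutation and phasing rows.
#'
#' @param mutations cohort mutation data.frame (column \code{sample_id}).
#' @param genomics cohort genomics data.frame (one row per sample).
#' @param phasing optional cohort phasing data.frame.
#' @param gene target gene symbol.
#' @return a data.frame with one row per sample (\code{sample_id},
#'   \code{b2m_status}, \code{biallelic_class},
#'   \code{clonal_nonsynonymous_count}, \code{n_mutations}); the full
#'   per-sample call objects are in \code{attr(, "calls")}.
#' @export
call_allelic_status_cohort <- function(mutations, genomics, phasing = NULL,
                                       gene = "B2M") {
  calls <- lapply(seq_len(nrow(genomics)), function(i) {
    sid <- genomics$sample_id[i]
    m <- mutations[mutations$sample_id == sid, , drop = FALSE]
    p <- if (!is.null(phasing) && nrow(phasing))
      phasing[phasing$sample_id == sid, , drop = FALSE] else NULL
    classify_allelic_status(m, genomics[i, , drop = FALSE], p, gene = gene)
  })
  out <- data.frame(
    sample_id = genomics$sample_id,
    b2m_status = vapply(calls, `[[`, "", "b2m_status"),
    biallelic_class = vapply(calls, `[[`, "", "biallelic_class"),
    clonal_nonsynonymous_count = vapply(calls, `[[`, 0L,
                                        "clonal_nonsynonymous_count"),
    n_mutations = vapply(calls, function(cl) length(cl$mut_cn_per_mutation),
                         0L),
    stringsAsFactors = FALSE)
  attr(out, "calls") <- calls
  out
}
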