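# Fixture builders (all in code; no files).

# A sample's mutation table at chosen mutation copy numbers. With
# purity 0.5 and vaf = mut_cn / 4, round(2 vaf / purity) recovers mut_cn
# exactly for mut_cn 0..4.
fx_purity <- 0.5

fx_mutations <- function(mut_cn, effect = NULL, subp = NULL,
                         sample_id = "S1", gene = "B2M") {
  k <- length(mut_cn)
  if (k == 0)
    return(data.frame(sample_id = character(0), mutation_id = character(0),
                      gene = character(0), vaf = numeric(0),
                      effect = character(0),
                      subclonal_probability = numeric(0)))
  data.frame(sample_id = sample_id,
             mutation_id = paste0("m", seq_len(k)),
             gene = gene, vaf = mut_cn / 4,
             effect = effect %||% rep("non_synonymous", k),
             subclonal_probability = subp %||% rep(0, k),
             stringsAsFactors = FALSE)
}

fx_genomics <- function(gene_total_cn = 2L, gene_minor_cn = 1L,
                        sample_id = "S1", purity = fx_purity) {
  data.frame(sample_id = sample_id, purity = purity,
             gene_total_cn = gene_total_cn, gene_minor_cn = gene_minor_cn,
             megabases_sequenced = 2859, stringsAsFactors = FALSE)
}

# Phasing rows for every pair, from an n x n relation matrix.
fx_phasing <- function(rel, sample_id = "S1") {
  n <- nrow(rel)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    counts <- switch(rel[i, j],
                     cis = c(2L, 0L, 0L, 3L),
                     trans = c(0L, 2L, 3L, 1L),
                     unphaseable = c(0L, 0L, 0L, 0L))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample_id,
      mutation_id_a = paste0("m", i), mutation_id_b = paste0("m", j),
      spanning_reads_both_alt = counts[1],
      spanning_reads_a_only = counts[2],
      spanning_reads_b_only = counts[3],
      spanning_reads_neither = counts[4], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The printed DRUP-style cohort: 21 mutant (20 CB / 1 NCB; responses
# 3 CR, 12 PR, 5 SD, 1 PD), 50 wildtype (31 CB / 19 NCB).
fx_drup_cohort <- function() {
  ids <- sprintf("P%02d", 1:71)
  status <- c(rep("mutant", 21), rep("wildtype", 50))
  cb <- c(rep("CB", 20), "NCB", rep("CB", 31), rep("NCB", 19))
  response <- c(rep("CR", 3), rep("PR", 12), rep("SD", 5), "PD",
                rep("SD", 31), rep("PD", 19))
  list(calls = data.frame(sample_id = ids, b2m_status = status,
                          stringsAsFactors = FALSE),
       clinical = data.frame(sample_id = ids, clinical_benefit = cb,
                             response = response, stringsAsFactors = FALSE))
}

# All enumeration configurations for the classifier truth table.
fx_enumeration_grid <- function(max_muts = 3) {
  rels <- c("cis", "trans", "unphaseable")
  out <- list()
  for (n in 1:max_muts) {
    mc_grid <- do.call(expand.grid, rep(list(0:4), n))
    n_pairs <- n * (n - 1) / 2
    rel_grid <- if (n_pairs > 0)
      do.call(expand.grid, c(rep(list(rels), n_pairs),
                             stringsAsFactors = FALSE))
    else data.frame(row.names = 1)
    for (cn in 1:4) for (minor in c(0L, 1L))
      for (i in seq_len(nrow(mc_grid))) for (j in seq_len(nrow(rel_grid))) {
        rel <- matrix(NA_character_, n, n)
        if (n_pairs > 0) {
          vals <- unlist(rel_grid[j, ], use.names = FALSE)
          k <- 0
          for (a in seq_len(n - 1)) for (b in (a + 1):n) {
            k <- k + 1
            rel[a, b] <- rel[b, a] <- vals[k]
          }
        }
        out[[length(out) + 1L]] <- list(
          mut_cn = as.integer(unlist(mc_grid[i, ], use.names = FALSE)),
          rel = rel, gene_cn = cn, minor_cn = minor)
      }
  }
  out
}
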