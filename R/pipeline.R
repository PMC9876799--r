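#' Format a percentage the way clinical tables print it
#'
#' Integer percent, except values below 10% which keep one decimal
#' (so 20/21 prints as 95 and 1/21 as 4.8).
#'
#' @param x percentage values (0-100 scale).
#' @return numeric vector rounded to the printed precision.
#' @export
format_percent <- function(x) ifelse(x < 10, round(x, 1), round(x))

#' Cross-tabulate allelic status against clinical benefit
#'
#' Builds the 2x2 table (rows mutant/wildtype, columns CB/NCB) from a calls
#' table and a clinical table joined on \code{sample_id}, with per-arm
#' benefit rates as printed percentages. Samples with a call but no outcome
#' are excluded with a warning and counted in the metadata.
#'
#' @param calls data.frame from [call_allelic_status_cohort()] (columns
#'   \code{sample_id}, \code{b2m_status}).
#' @param clinical data.frame with \code{sample_id} and
#'   \code{clinical_benefit} ("CB"/"NCB").
#' @return list with \code{table} (2x2 integer matrix), \code{rates}
#'   (per-arm CB percentage, printed precision; \code{NA} for an empty
#'   arm), \code{rates_raw} and \code{n_excluded}.
#' @export
crosstab_cb <- function(calls, clinical) {
  df <- merge(calls[, c("sample_id", "b2m_status")],
              clinical[, c("sample_id", "clinical_benefit")],
              by = "sample_id", all.x = TRUE)
  excl <- is.na(df$clinical_benefit)
  if (any(excl))
    warn_(sum(excl), " called sample(s) lack an outcome; excluded")
  df <- df[!excl, , drop = FALSE]
  if (!all(df$clinical_benefit %in% c("CB", "NCB")))
    stop_("clinical_benefit must be 'CB' or 'NCB'")
  tab <- matrix(0L, 2, 2, dimnames = list(c("mutant", "wildtype"),
                                          c("CB", "NCB")))
  for (s in rownames(tab)) for (o in colnames(tab))
    tab[s, o] <- sum(df$b2m_status == s & df$clinical_benefit == o)
  arm_n <- rowSums(tab)
  raw <- ifelse(arm_n > 0, 100 * tab[, "CB"] / arm_n, NA_real_)
  list(table = tab, rates = format_percent(raw), rates_raw = raw,
       n_excluded = sum(excl))
}

#' Tabulate best-overall-response categories
#'
#' Counts and printed percentages of RECIST categories (CR, PR, SD, PD),
#' optionally within arms.
#'
#' @param response character vector of categories; values outside
#'   \{CR, PR, SD, PD\} are an error.
#' @param arm optional parallel vector of arm labels (e.g. B2M status); when
#'   supplied the tabulation is per arm.
#' @return a data.frame with columns \code{arm} (when given),
#'   \code{response}, \code{count}, \code{percent} (printed precision,
#'   within arm).
#' @export
tabulate_response <- function(response, arm = NULL) {
  lv <- c("CR", "PR", "SD", "PD")
  bad <- setdiff(unique(response), lv)
  if (length(bad))
    stop_("unknown response category: ", paste(bad, collapse = ", "))
  one_arm <- function(resp, label) {
    if (!length(resp))
      return(data.frame(arm = character(0), response = character(0),
                        count = integer(0), percent = numeric(0)))
    cnt <- table(factor(resp, levels = lv))
    keep <- cnt > 0
    data.frame(arm = label, response = names(cnt)[keep],
               count = as.integer(cnt[keep]),
               percent = format_percent(100 * as.integer(cnt[keep]) /
                                          length(resp)),
               stringsAsFactors = FALSE)
  }
  if (is.null(arm)) return(one_arm(response, "all"))
  do.call(rbind, lapply(sort(unique(arm)), function(a)
    one_arm(response[arm == a], a)))
}

#' Pipeline configuration
#'
#' Either simulate inputs (supply \code{simulation}) or load them from TSV
#' files (supply \code{input_dir} written in the layout of
#' [write_cohort()]).
#'
#' @param output_dir directory for all stage outputs.
#' @param simulation a [simulation_config()], or NULL to read inputs.
#' @param input_dir directory holding mutations/genomics/phasing/expression/
#'   clinical TSVs (see [write_cohort()]).
#' @param gene target gene symbol.
#' @param gmt_path optional GMT of base marker sets.
#' @param cluster_k clusters to cut the Ward tree into (2 = high/low).
#' @param seed integer seed for any stochastic stage.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(output_dir, simulation = NULL, input_dir = NULL,
                            gene = "B2M", gmt_path = NULL, cluster_k = 2,
                            seed = 1L) {
  if (is.null(simulation) && is.null(input_dir))
    stop_("provide either a simulation config or an input directory")
  if (!is.null(gmt_path) && !file.exists(gmt_path))
    stop_("GMT file not found: ", gmt_path)
  structure(list(output_dir = output_dir, simulation = simulation,
                 input_dir = input_dir, gene = gene, gmt_path = gmt_path,
                 cluster_k = cluster_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_cohort_inputs <- function(dir) {
  mutations <- read_tsv_strict(file.path(dir, "mutations.tsv"),
                               c("sample_id", "mutation_id", "gene", "vaf",
                                 "effect"))
  genomics <- read_tsv_strict(file.path(dir, "genomics.tsv"),
                              c("sample_id", "purity", "gene_total_cn"))
  ph_path <- file.path(dir, "phasing.tsv")
  phasing <- if (file.exists(ph_path))
    read_tsv_strict(ph_path, c("sample_id", "mutation_id_a",
                               "mutation_id_b")) else NULL
  expr <- read_tsv_strict(file.path(dir, "expression.tsv"), "gene")
  counts <- as.matrix(expr[, -1, drop = FALSE])
  rownames(counts) <- expr$gene
  ls_path <- file.path(dir, "library_sizes.tsv")
  lib <- if (file.exists(ls_path)) {
    l <- read_tsv_strict(ls_path, c("sample_id", "library_size"))
    stats::setNames(l$library_size, l$sample_id)[colnames(counts)]
  } else colSums(counts)
  clinical <- read_tsv_strict(file.path(dir, "clinical.tsv"),
                              c("sample_id", "clinical_benefit"))
  list(mutations = mutations, genomics = genomics, phasing = phasing,
       expression = list(counts = counts, library_sizes = lib),
       clinical = clinical)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> allelic-status calling -> gene-set
#' scoring and Ward clustering -> the association battery, and writes every
#' stage output (TSVs plus a JSON report) under the configured output
#' directory. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return the report, an object of class \code{cohort_report} (invisible
#'   copy of what is serialized to \code{report.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop_(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))))

  inputs <- stage("inputs", {
    if (!is.null(config$simulation)) {
      cohort <- simulate_cohort(config$simulation)
      write_cohort(cohort, file.path(config$output_dir, "inputs"))
      cohort
    } else read_cohort_inputs(config$input_dir)
  })

  calls <- stage("call_allelic_status", suppressWarnings(
    call_allelic_status_cohort(inputs$mutations, inputs$genomics,
                               inputs$phasing, gene = config$gene)))
  calls$tmb <- if (!is.null(inputs$clinical$tmb))
    inputs$clinical$tmb[match(calls$sample_id,
                              inputs$clinical$sample_id)] else NA_real_
  write_tsv(calls, file.path(config$output_dir, "calls.tsv"))
  evidence <- lapply(attr(calls, "calls"), function(x)
    x[c("sample_id", "b2m_status", "biallelic_class", "evidence")])
  jsonlite::write_json(evidence,
                       file.path(config$output_dir, "evidence.json"),
                       auto_unbox = TRUE, digits = NA)

  scores <- stage("score_sets", {
    base_sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
      else list()
    sets <- assemble_default_sets(rownames(inputs$expression$counts),
                                  base_sets)
    suppressWarnings(score_sets(inputs$expression$counts, sets,
                                normalize = TRUE,
                                library_sizes =
                                  inputs$expression$library_sizes))
  })
  write_tsv(data.frame(set = rownames(scores), scores, check.names = FALSE),
            file.path(config$output_dir, "scores.tsv"))

  clustering <- stage("cluster", {
    z <- suppressWarnings(zscore_rows(scores[stats::complete.cases(scores), ,
                                             drop = FALSE]))
    ward_cluster(z, k = config$cluster_k)
  })
  write_tsv(data.frame(sample_id = names(clustering$labels),
                       cluster = unname(clustering$labels)),
            file.path(config$output_dir, "clusters.tsv"))
  writeLines(clustering$newick, file.path(config$output_dir,
                                          "linkage.newick"))

  assoc <- stage("associate", {
    cl <- merge(calls, inputs$clinical, by = "sample_id")
    cl <- cl[order(cl$sample_id), , drop = FALSE]
    status <- cl$b2m_status
    xt <- suppressWarnings(crosstab_cb(calls, inputs$clinical))
    out <- list(crosstab = xt,
                fisher_cb = fisher_exact_2x2(xt$table))
    if (!is.null(cl$tmb.y) || !is.null(cl$tmb)) {
      tmb <- cl$tmb.y %||% cl$tmb
      out$wilcoxon_tmb <- wilcoxon_rank_sum(tmb[status == "mutant"],
                                            tmb[status == "wildtype"])
      out$logistic_cb_tmb <- logistic_cb(cl$clinical_benefit, status,
                                         data.frame(tmb = tmb))
    }
    sc <- scores[, cl$sample_id, drop = FALSE]
    per_set <- lapply(rownames(sc), function(s) {
      v <- sc[s, ]
      if (anyNA(v)) return(NULL)
      wilcoxon_rank_sum(v[status == "mutant"], v[status == "wildtype"])
    })
    names(per_set) <- rownames(sc)
    per_set <- Filter(Negate(is.null), per_set)
    ps <- vapply(per_set, `[[`, 0, "p_value")
    out$set_tests <- data.frame(set = names(per_set),
                                u_statistic = vapply(per_set, `[[`, 0,
                                                     "estimate"),
                                p_value = ps,
                                p_adjusted = benjamini_hochberg(ps),
                                stringsAsFactors = FALSE)
    if (!is.null(cl$response))
      out$response <- tabulate_response(cl$response, arm = status)
    out
  })
  write_tsv(assoc$set_tests, file.path(config$output_dir,
                                       "set_associations.tsv"))

  report <- list(
    n_samples = nrow(inputs$genomics),
    n_mutant = sum(calls$b2m_status == "mutant"),
    cb_table = assoc$crosstab$table,
    cb_rates_percent = assoc$crosstab$rates,
    fisher_p = assoc$fisher_cb$p_value,
    set_tests = assoc$set_tests,
    response = assoc$response,
    cluster_sizes = table(clustering$labels),
    metadata = list(package_version =
                      as.character(utils::packageVersion("b2mscan")),
                    seed = config$seed, gene = config$gene,
                    simulated = !is.null(config$simulation)))
  class(report) <- "cohort_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report:", x$n_samples, "samples,", x$n_mutant, "mutant\n")
  print(x$cb_table)
  cat("arm CB rates (%):", paste(names(x$cb_rates_percent),
                                 x$cb_rates_percent, sep = "=",
                                 collapse = ", "), "\n")
  cat("Fisher p =", format(x$fisher_p, digits = 3), "\n")
  invisible(x)
}
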