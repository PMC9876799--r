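#' Reads-per-million normalization
#'
#' Scales each sample (column) of a raw-count matrix to reads per million:
#' \code{count * 1e6 / library_size}. When library sizes are the column
#' totals, each column of the result sums to 1e6.
#'
#' @param counts numeric matrix, genes x samples, raw counts.
#' @param library_sizes per-sample total mapped reads; defaults to column
#'   sums. Zero library sizes are an error.
#' @return matrix in RPM units.
#' @export
rpm <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_("counts must be non-negative")
  if (anyDuplicated(rownames(counts)))
    stop_("duplicate gene symbols in expression matrix")
  ls <- library_sizes %||% colSums(counts)
  if (length(ls) != ncol(counts))
    stop_("library_sizes length does not match sample count")
  if (any(ls <= 0)) stop_("zero or negative library size")
  sweep(counts, 2, ls, function(x, s) x * 1e6 / s)
}

#' Parse a GMT gene-set file
#'
#' @param path GMT path (tab-separated: set name, description, genes...).
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop_("duplicate set names in GMT")
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Build the killer-cell immunoglobulin-like receptor (KIR) gene set
#'
#' Selects every symbol that starts with "KIR" and contains "DL" or "DS"
#' (inhibitory long-tail / activating short-tail receptors). Pseudo-family
#' members such as KIR3DX1 and unrelated symbols such as KIRREL1 fail the
#' substring test. Case-sensitive on official symbols.
#'
#' @param gene_universe character vector of gene symbols.
#' @return character vector of KIR symbols (empty, with a warning, when
#'   none match).
#' @export
build_kir_set <- function(gene_universe) {
  hits <- gene_universe[startsWith(gene_universe, "KIR") &
                          grepl("DL|DS", gene_universe)]
  if (length(hits) == 0) warn_("no KIR genes found in gene universe")
  unique(hits)
}

#' Assemble the immune marker gene-set collection
#'
#' Applies the fixed edits on top of a user-supplied base collection of
#' immune marker sets: adds a CD4+ T cell set (\code{CD4}), a
#' "γδ1/3 T cells" set (\code{TRDV1}, \code{TRDV3}) and the
#' rule-built KIR set; removes any "NK CD56dim cells" set (redundant with
#' the full KIR set); rebuilds the NK set around \code{NCR1} and
#' \code{KLRF1}, stripping XCL1/XCL2 (also accepted under the XLC1/XLC2
#' spelling) which are highly expressed by tumour-infiltrating gamma-delta
#' T cells; and fixes the cytotoxicity set to the genes encoding cytotoxic
#' molecules (\code{GZMA}, \code{GZMB}, \code{GZMH}, \code{PRF1},
#' \code{GNLY}, \code{CTSW}).
#'
#' @param gene_universe symbols available in the expression matrix (used to
#'   build the KIR set).
#' @param base_sets named list of base marker sets (e.g. from [read_gmt()]);
#'   may be empty, in which case only the rule-built sets are returned.
#' @return named list of gene sets; duplicate names are an error.
#' @export
assemble_default_sets <- function(gene_universe, base_sets = list()) {
  sets <- base_sets
  drop <- grepl("^NK CD56", names(sets))
  sets <- sets[!drop]
  nk_name <- grep("^NK cells$", names(sets), value = TRUE)
  if (length(nk_name)) {
    nk <- setdiff(sets[[nk_name]], c("XCL1", "XCL2", "XLC1", "XLC2"))
    sets[[nk_name]] <- unique(c(nk, "KLRF1"))
  } else {
    sets[["NK cells"]] <- c("NCR1", "KLRF1")
  }
  sets[["Cytotoxic cells"]] <- c("GZMA", "GZMB", "GZMH", "PRF1", "GNLY",
                                 "CTSW")
  sets[["CD4 T cells"]] <- "CD4"
  sets[["γδ1/3 T cells"]] <- c("TRDV1", "TRDV3")
  sets[["KIR"]] <- build_kir_set(gene_universe)
  if (anyDuplicated(names(sets)))
    stop_("duplicate gene-set names after assembly: ",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' Score samples with marker gene sets (mean log2[RPM + 1])
#'
#' The infiltration score of a set in a sample is the arithmetic mean of
#' \code{log2(RPM + 1)} over the set's genes present in the matrix. Genes
#' absent from the matrix are dropped with a warning; a set with no present
#' gene scores \code{NA} (not zero).
#'
#' @param expr expression matrix, genes x samples. RPM units by default;
#'   pass raw counts with \code{normalize = TRUE} (and optionally
#'   \code{library_sizes}) to normalize first.
#' @param sets named list of gene sets.
#' @param normalize apply [rpm()] first.
#' @param library_sizes forwarded to [rpm()] when normalizing.
#' @return matrix of scores, sets x samples, with the genes actually used
#'   per set in \code{attr(, "genes_used")}.
#' @export
score_sets <- function(expr, sets, normalize = FALSE, library_sizes = NULL) {
  expr <- as.matrix(expr)
  if (anyDuplicated(rownames(expr))) stop_("duplicate gene symbols")
  if (normalize) expr <- rpm(expr, library_sizes)
  lg <- log2(expr + 1)
  used <- lapply(names(sets), function(n) intersect(sets[[n]], rownames(lg)))
  names(used) <- names(sets)
  for (n in names(sets)) {
    missing <- setdiff(sets[[n]], rownames(lg))
    if (length(missing))
      warn_(sprintf("set '%s': %d gene(s) absent from matrix (%s)", n,
                    length(missing), paste(missing, collapse = ", ")))
  }
  out <- t(vapply(names(sets), function(n) {
    if (length(used[[n]]) == 0) return(rep(NA_real_, ncol(lg)))
    colMeans(lg[used[[n]], , drop = FALSE])
  }, numeric(ncol(lg))))
  dimnames(out) <- list(names(sets), colnames(lg))
  attr(out, "genes_used") <- used
  out
}

#' Z-score matrix rows
#'
#' Centres and scales each row to mean 0, population standard deviation 1
#' (divisor n, not n - 1). Constant rows map to all zeros with a warning.
#'
#' @param table numeric matrix with >= 2 columns.
#' @return Z-scored matrix of the same shape.
#' @export
zscore_rows <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) < 2) stop_("Z-scoring needs >= 2 samples")
  mu <- rowMeans(table)
  sd_pop <- sqrt(rowMeans((table - mu)^2))
  flat <- sd_pop == 0
  if (any(flat)) {
    warn_(sum(flat), " constant row(s) mapped to zeros")
    sd_pop[flat] <- 1
  }
  (table - mu) / sd_pop
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the columns (samples) of a score matrix
#' using Euclidean distance and Ward's minimum-variance criterion
#' (\code{hclust} method \code{"ward.D2"}, which operates on unsquared
#' Euclidean distances). Cutting at \code{k = 2} labels the cluster with
#' the larger mean score "high" and the other "low" (high- vs
#' low-infiltration groups).
#'
#' @param table numeric matrix, features x samples.
#' @param k number of clusters (1 <= k <= number of samples).
#' @return list with \code{labels} (named character/integer vector per
#'   sample), \code{hclust} (the linkage tree) and \code{newick} (the tree
#'   in Newick text, heights as branch lengths).
#' @export
ward_cluster <- function(table, k = 2) {
  table <- as.matrix(table)
  n <- ncol(table)
  if (k < 1) stop_("'k' must be >= 1")
  if (k > n) stop_("'k' exceeds the number of samples")
  if (is.null(colnames(table))) colnames(table) <- paste0("S", seq_len(n))
  hc <- stats::hclust(stats::dist(t(table)), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  labels <- as.character(grp)
  if (k == 2) {
    m <- tapply(colMeans(table, na.rm = TRUE), grp, mean)
    hi <- names(m)[which.max(m)]
    labels <- ifelse(grp == hi, "high", "low")
  }
  names(labels) <- colnames(table)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(labels = labels, hclust = hc, newick = nwk)
}
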