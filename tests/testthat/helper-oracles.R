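# Independent oracles. Each is coded from the definition, along a different
# route than the package implementation it checks.

# Fisher two-sided p by explicit hypergeometric enumeration (factorials,
# not dhyper): probability-mass method over all tables with fixed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  if (min(r1, r2, k, b + d) == 0) return(1.0)
  lo <- max(0, k - r2); hi <- min(k, r1)
  logp <- function(x) lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k)
  xs <- lo:hi
  lp <- vapply(xs, logp, 0)
  sum(exp(lp)[lp <= logp(a) + 1e-7])
}

# Wilcoxon exact two-sided p by enumerating which pooled elements are
# assigned to x, counting Mann-Whitney pair wins directly.
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  centre <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, u_of)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Benjamini-Hochberg by the direct step-up definition: for the i-th
# smallest p, the adjusted value is min over j >= i of min(1, m p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- best
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Logistic MLE by hand-coded Newton-Raphson IRLS on a design matrix.
oracle_irls_logistic <- function(X, y, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    beta_new <- unname(drop(solve(crossprod(X, X * W),
                                  crossprod(X, W * z))))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Brute-force Ward clustering: at each step merge the pair of clusters
# whose union minimizes the increase in within-cluster sum of squares.
# Returns the partition (canonical labels) after each merge.
oracle_ward_partitions <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  canon <- function(cl) {
    lab <- integer(n)
    for (g in cl) lab[g] <- min(g)
    lab
  }
  parts <- list()
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        ca <- colMeans(X[A, , drop = FALSE])
        cb <- colMeans(X[B, , drop = FALSE])
        d <- length(A) * length(B) / (length(A) + length(B)) *
          sum((ca - cb)^2)
        if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
      }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    parts[[length(parts) + 1L]] <- canon(clusters)
  }
  parts
}

# Partition sequence of an hclust tree, canonicalized the same way.
hclust_partitions <- function(hc, n) {
  lapply(seq_len(n - 1), function(s) {
    grp <- stats::cutree(hc, k = n - s)
    lab <- integer(n)
    for (g in unique(grp)) lab[grp == g] <- min(which(grp == g))
    lab
  })
}

# Independent transcription of the three-subgroup biallelic rules.
# mut_cn: integer vector of clonal non-synonymous mutation copy numbers;
# rel: n x n matrix of "cis"/"trans"/"unphaseable"; minor_cn 0 forces LOH.
oracle_classify <- function(mut_cn, rel, gene_cn, minor_cn) {
  n <- length(mut_cn)
  if (gene_cn == 0) return(c("mutant", "biallelic"))
  if (n == 0) return(c("wildtype", "not_applicable"))
  loh <- (mut_cn >= gene_cn) | (minor_cn == 0)
  if (n == 1)
    return(c("mutant", if (loh[1]) "biallelic" else "not_biallelic"))
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (rel[i, j] == "cis" && grp[i] != grp[j]) {
        grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
        changed <- TRUE
      }
    if (!changed) break
  }
  reps <- vapply(unique(grp), function(g) {
    idx <- which(grp == g)
    idx[which.max(mut_cn[idx])]
  }, 0L)
  cn_sum <- sum(mut_cn[reps])
  trans_any <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (grp[i] != grp[j] && rel[i, j] == "trans") trans_any <- TRUE
  cls <- if (any(loh)) "biallelic"
  else if (length(reps) > 1 && trans_any && cn_sum >= gene_cn) "biallelic"
  else if (length(reps) > 1 && !trans_any && cn_sum >= gene_cn)
    "potentially_biallelic"
  else "not_biallelic"
  c("mutant", cls)
}
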