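new_assoc_result <- function(test_name, estimate, p_value, adjustment,
                             n, ...) {
  out <- list(test_name = test_name, estimate = estimate, p_value = p_value,
              adjustment = adjustment, n = n, ...)
  class(out) <- "assoc_result"
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %s, p = %s, n = %d%s\n", x$test_name,
              format(x$estimate, digits = 4),
              format(x$p_value, digits = 4), x$n,
              if (length(x$adjustment))
                paste0(" (adjusted for ",
                       paste(x$adjustment, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact test of independence with fixed margins. The two-sided p-value is
#' the probability-mass definition: the sum of hypergeometric probabilities
#' of all tables (with the observed margins) whose probability does not
#' exceed that of the observed table. The reported estimate is the sample
#' odds ratio \code{ad / bc} (\code{Inf} when \code{bc = 0}).
#'
#' @param table 2x2 matrix of non-negative counts, rows = mutant/wildtype,
#'   columns = benefit/no-benefit (or any two binary factors).
#' @param haldane add 0.5 to every cell for the odds ratio (never for the
#'   p-value) instead of reporting Inf/0 on zero cells.
#' @return an \code{assoc_result}; a zero margin yields p = 1 with a
#'   warning.
#' @examples
#' fisher_exact_2x2(matrix(c(20, 1, 31, 19), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table, haldane = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop_("'table' must be a 2x2 matrix of non-negative integer counts")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  if (n < 1) stop_("empty table")
  est <- if (haldane) ((a + .5) * (d + .5)) / ((b + .5) * (c + .5)) else
    (a * d) / (b * c)
  if (min(a + b, c + d, a + c, b + d) == 0) {
    warn_("zero margin in 2x2 table; p = 1 by convention")
    return(new_assoc_result("fisher_exact", est, 1.0, character(0), n))
  }
  m <- a + b; k <- a + c
  supp <- max(0, k - (c + d)):min(k, m)
  pr <- stats::dhyper(supp, m, c + d, k)
  p_obs <- stats::dhyper(a, m, c + d, k)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  new_assoc_result("fisher_exact", est, p, character(0), n)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact by full enumeration of rank-sum assignments when the pooled sample
#' size is at most 20 and there are no ties; otherwise the normal
#' approximation with mid-ranks, tie-corrected variance and continuity
#' correction. The estimate is the Mann-Whitney U statistic of \code{x}.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force (TRUE) or forbid (FALSE) the exact branch; default
#'   chooses automatically.
#' @return an \code{assoc_result}; identical pooled values give p = 1.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop_("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(new_assoc_result("wilcoxon_rank_sum", u, 1.0, character(0), n))
  ties <- anyDuplicated(pooled) > 0
  use_exact <- exact %||% (n <= 20 && !ties)
  if (use_exact && ties)
    stop_("exact branch is undefined in the presence of ties")
  if (use_exact) {
    # enumerate all C(n, nx) rank-sum assignments; null is symmetric
    combos <- utils::combn(n, nx)
    ws <- colSums(matrix(r[combos], nrow = nx))
    mu <- nx * (n + 1) / 2
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    mu_u <- nx * ny / 2
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    var_u <- nx * ny / 12 * (n + 1 - tie_term)
    if (var_u == 0)
      return(new_assoc_result("wilcoxon_rank_sum", u, 1.0, character(0), n))
    z <- (u - mu_u - sign(u - mu_u) * 0.5) / sqrt(var_u)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_assoc_result("wilcoxon_rank_sum", u, p, character(0), n)
}

#' Logistic regression of clinical benefit on allelic status
#'
#' Maximum-likelihood logistic fit (binomial IRLS via \code{stats::glm}) of
#' a binary outcome on mutation status plus optional covariates (e.g.
#' continuous TMB and/or the primary tumour site). Categorical covariates
#' are dummy-coded against the lexicographically first level. Reports the
#' status coefficient, its odds ratio and the Wald two-sided p-value.
#' Perfect separation is flagged and the p-value reported as \code{NA}.
#'
#' @param outcome binary vector (0/1, logical, or "CB"/"NCB").
#' @param b2m binary mutation-status vector (0/1, logical, or
#'   "mutant"/"wildtype").
#' @param covariates optional data.frame of adjustment columns.
#' @return an \code{assoc_result} with extra fields \code{odds_ratio},
#'   \code{coefficients} and \code{separation}.
#' @export
logistic_cb <- function(outcome, b2m, covariates = NULL) {
  y <- to_binary(outcome, positive = c("1", "TRUE", "CB", "yes"))
  if (length(unique(y)) < 2) stop_("outcome needs both classes")
  s <- to_binary(b2m, positive = c("1", "TRUE", "mutant", "MUT"))
  df <- data.frame(.y = y, .b2m = s)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(col)
      if (is.character(col)) factor(col, levels = sort(unique(col))) else col)
    df <- cbind(df, covariates)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # glm's warning misses small separated fits; inspect fitted values too
  sep <- sep || !fit$converged ||
    all(abs(fit$fitted.values - df$.y) < 1e-6)
  sm <- summary(fit)$coefficients
  est <- sm[".b2m", "Estimate"]
  p <- if (sep) NA_real_ else sm[".b2m", "Pr(>|z|)"]
  new_assoc_result("logistic_regression", est, p,
                   adjustment = setdiff(names(df), c(".y", ".b2m")),
                   n = length(y), odds_ratio = exp(est),
                   coefficients = stats::coef(fit), separation = sep)
}

to_binary <- function(x, positive) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop_("numeric binary vector must be 0/1")
    return(as.integer(x))
  }
  as.integer(as.character(x) %in% positive)
}

#' OLS regression of a score on allelic status with covariates
#'
#' Ordinary least squares with an intercept; the reported p-value is the
#' two-sided t-test of the status term. With no covariates this reduces to
#' the pooled-variance two-sample t-test. A rank-deficient design is an
#' error naming the collinear columns.
#'
#' @param y numeric response (e.g. a gene-set score).
#' @param b2m binary status vector.
#' @param covariates optional data.frame (factors dummy-coded against the
#'   lexicographically first level).
#' @return an \code{assoc_result} with extra field \code{coefficients}.
#' @export
lm_adjusted <- function(y, b2m, covariates = NULL) {
  s <- to_binary(b2m, positive = c("1", "TRUE", "mutant", "MUT"))
  df <- data.frame(.y = y, .b2m = s)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(col)
      if (is.character(col)) factor(col, levels = sort(unique(col))) else col)
    df <- cbind(df, covariates)
  }
  X <- stats::model.matrix(.y ~ ., data = df)
  if (nrow(X) <= ncol(X)) stop_("not enough observations for the design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_("rank-deficient design; collinear column(s): ",
          paste(bad, collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  new_assoc_result("linear_regression", sm[".b2m", "Estimate"],
                   sm[".b2m", "Pr(>|t|)"],
                   adjustment = setdiff(names(df), c(".y", ".b2m")),
                   n = length(y), coefficients = stats::coef(fit))
}

#' Mixed model with random intercepts per grouping factor
#'
#' REML fit of \code{y ~ status + (1|group)} (one term per grouping factor,
#' e.g. tumour type and biopsy site) via \code{lme4::lmer}. Grouping
#' factors with fewer than two levels are dropped with a message; with no
#' usable factor the model degrades to ordinary least squares, whose status
#' estimate it then equals. The fixed-effect p-value is the Wald normal
#' approximation (lme4 reports no denominator df). Non-convergence is
#' flagged in the result.
#'
#' @param y numeric response.
#' @param b2m binary status vector.
#' @param groups data.frame with one or two grouping columns.
#' @return an \code{assoc_result} with extra fields \code{variance_components}
#'   (named vector, one per retained factor plus \code{residual}),
#'   \code{converged} and \code{method} ("REML" or "OLS-degenerate").
#' @export
lmm_random_intercepts <- function(y, b2m, groups) {
  s <- to_binary(b2m, positive = c("1", "TRUE", "mutant", "MUT"))
  groups <- as.data.frame(groups)
  usable <- vapply(groups, function(g) length(unique(g)) >= 2, TRUE)
  if (any(!usable))
    message("dropping grouping factor(s) with a single level: ",
            paste(names(groups)[!usable], collapse = ", "))
  groups <- groups[, usable, drop = FALSE]
  if (ncol(groups) == 0) {
    ols <- lm_adjusted(y, s)
    return(new_assoc_result("linear_mixed_model", ols$estimate, ols$p_value,
                            adjustment = character(0), n = length(y),
                            variance_components = c(residual =
                              stats::var(stats::residuals(
                                stats::lm(y ~ s)))),
                            converged = TRUE, method = "OLS-degenerate"))
  }
  df <- data.frame(.y = y, .b2m = s, groups)
  form <- stats::as.formula(paste(".y ~ .b2m +",
                                  paste(sprintf("(1|%s)", names(groups)),
                                        collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  if (!conv) warn_("mixed model did not converge cleanly")
  sm <- summary(fit)$coefficients
  est <- sm[".b2m", "Estimate"]
  z <- sm[".b2m", "t value"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcs <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                         vc$grp))
  new_assoc_result("linear_mixed_model", est, 2 * stats::pnorm(-abs(z)),
                   adjustment = names(groups), n = length(y),
                   variance_components = vcs, converged = conv,
                   method = "REML")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: \code{p_(i) * m / i} cumulatively
#' minimized from the largest rank down, capped at 1. NAs propagate.
#'
#' @param p_values vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- p_values
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_("p-values must lie in [0, 1]")
  m <- sum(ok)
  if (m == 0) return(p)
  idx <- order(p[ok], decreasing = TRUE)
  adj <- pmin(1, cummin(p[ok][idx] * m / seq(m, 1)))
  out <- p
  out[ok][idx] <- adj
  out
}
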