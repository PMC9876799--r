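test_that("fisher_exact_2x2 reproduces known tables", {
  # the printed benefit table: mutant 20/1, wildtype 31/19
  r <- fisher_exact_2x2(matrix(c(20, 1, 31, 19), 2, byrow = TRUE))
  expect_equal(signif(r$p_value, 2), 0.0038)
  expect_equal(r$estimate, (20 * 19) / (1 * 31))
  # symmetric table
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1.0)
  # fully crossed: only two equally extreme tables exist
  r2 <- fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_equal(r2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_warning(rz <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)), "margin")
  expect_equal(rz$p_value, 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  # odds-ratio conventions on zero cells
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 2, 3), 2,
                                       byrow = TRUE))$estimate, Inf)
  rh <- fisher_exact_2x2(matrix(c(5, 0, 2, 3), 2, byrow = TRUE),
                         haldane = TRUE)
  expect_equal(rh$estimate, (5.5 * 3.5) / (0.5 * 2.5))
})

test_that("fisher_exact_2x2 equals enumeration and stats::fisher.test", {
  set.seed(7)
  for (i in 1:60) {
    t4 <- rpois(4, 5)
    if (sum(t4) == 0) next
    tab <- matrix(t4, 2)
    mine <- suppressWarnings(fisher_exact_2x2(tab)$p_value)
    expect_equal(mine, oracle_fisher_p(t4[1], t4[3], t4[2], t4[4]),
                 tolerance = 1e-10)
    if (min(rowSums(tab), colSums(tab)) > 0)
      expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("wilcoxon exact branch matches enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2))$p_value, 1.0)
  set.seed(11)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- runif(nx); y <- runif(ny) + runif(1, -0.5, 0.5)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcoxon_p(x, y),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  expect_error(wilcoxon_rank_sum(c(1, 1, 2), c(3, 4), exact = TRUE), "ties")
})

test_that("wilcoxon normal approximation tracks enumeration at n = 8 + 8", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8, 0.8)
    exact <- wilcoxon_rank_sum(x, y)$p_value
    approx <- wilcoxon_rank_sum(x, y, exact = FALSE)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("logistic_cb fits by ML and matches a hand-coded IRLS", {
  # 30-row fixture with a continuous covariate
  set.seed(3)
  n <- 30
  b2m <- rep(0:1, 15)
  tmb <- rlnorm(n, 3, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * b2m + 0.01 * tmb))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  fit <- logistic_cb(y, b2m, data.frame(tmb = tmb))
  X <- cbind(1, tmb, b2m)  # same column space, different order
  beta <- oracle_irls_logistic(X, y)
  expect_equal(unname(fit$estimate), beta[3], tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), beta[1],
               tolerance = 1e-6)
  expect_equal(fit$odds_ratio, exp(fit$estimate))
  expect_identical(fit$adjustment, "tmb")
})

test_that("logistic_cb recovers a null coefficient and flags separation", {
  co <- simulate_cohort(simulation_config(n_samples = 5000, cb_beta_b2m = 0,
                                          seed = 31))
  fit <- logistic_cb(co$clinical$clinical_benefit, co$truth$b2m_status,
                     data.frame(tmb = co$clinical$tmb))
  expect_lt(abs(fit$estimate), 0.1)

  # intercept-only: 50% outcomes -> intercept ~ 0
  y <- rep(0:1, 50)
  f0 <- logistic_cb(y, rep(0:1, each = 50))
  expect_lt(abs(unname(f0$coefficients["(Intercept)"])), 0.3)

  # perfect separation
  sep <- logistic_cb(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separation)
  expect_true(is.na(sep$p_value))
})

test_that("lm_adjusted equals the pooled t-test without covariates", {
  set.seed(5)
  y <- rnorm(40); g <- rep(0:1, 20)
  fit <- lm_adjusted(y, g)
  tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(fit$estimate, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("lm_adjusted recovers a known effect and rejects collinearity", {
  set.seed(6)
  n <- 4000
  g <- rep(0:1, n / 2)
  site <- sample(c("colon", "liver", "lung"), n, replace = TRUE)
  y <- 1.0 * g + 0.5 * (site == "liver") + rnorm(n)
  fit <- lm_adjusted(y, g, data.frame(site = site))
  expect_lt(abs(fit$estimate - 1.0), 0.1)
  expect_error(lm_adjusted(y, g, data.frame(a = g, b = g)),
               "collinear")
})

test_that("mixed model degrades to OLS and recovers variance components", {
  set.seed(8)
  y <- rnorm(50); g <- rep(0:1, 25)
  one_level <- data.frame(grp = rep("only", 50))
  suppressMessages(mm <- lmm_random_intercepts(y, g, one_level))
  expect_identical(mm$method, "OLS-degenerate")
  expect_equal(mm$estimate, lm_adjusted(y, g)$estimate, tolerance = 1e-12)

  # zero between-group variance
  n <- 2000
  grp <- sample(letters[1:10], n, replace = TRUE)
  g2 <- rbinom(n, 1, 0.5)
  y2 <- 0.7 * g2 + rnorm(n)
  mm2 <- lmm_random_intercepts(y2, g2, data.frame(grp = grp))
  expect_lt(unname(mm2$variance_components["grp"]), 0.05)
  expect_lt(abs(mm2$estimate - 0.7), 0.15)

  # group sd 1.0, 50 groups x 40 samples
  grp3 <- rep(sprintf("g%02d", 1:50), each = 40)
  eff <- rnorm(50, 0, 1)
  g3 <- rbinom(2000, 1, 0.5)
  y3 <- 0.5 * g3 + eff[as.integer(factor(grp3))] + rnorm(2000)
  mm3 <- lmm_random_intercepts(y3, g3, data.frame(grp = grp3))
  expect_lt(abs(unname(mm3$variance_components["grp"]) - 1.0), 0.3)
  expect_identical(mm3$method, "REML")
})

test_that("benjamini_hochberg matches the direct formula and p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.5)), "0, 1")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # NAs pass through
  withna <- benjamini_hochberg(c(0.01, NA, 0.04))
  expect_true(is.na(withna[2]))
  expect_equal(withna[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
})

test_that("fisher type-I error is controlled on null 2x2 data", {
  set.seed(19)
  rejections <- 0
  n_tab <- 200
  for (i in 1:n_tab) {
    g <- rbinom(40, 1, 0.5); o <- rbinom(40, 1, 0.5)
    tab <- matrix(c(sum(g & o), sum(g & !o), sum(!g & o), sum(!g & !o)),
                  2, byrow = TRUE)
    p <- suppressWarnings(fisher_exact_2x2(tab)$p_value)
    rejections <- rejections + (p < 0.05)
  }
  # exact test is conservative; allow binomial slack above nominal 5%
  expect_lte(rejections / n_tab, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tab))
})
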