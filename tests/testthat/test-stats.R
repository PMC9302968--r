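make_long <- function(Y) {
  data.frame(participant = rep(seq_len(nrow(Y)), ncol(Y)),
             session = rep(colnames(Y) %||% paste0("s", seq_len(ncol(Y))),
                           each = nrow(Y)),
             value = as.vector(Y))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rmANOVA: identical values give F = 0; two sessions give t^2", {
  flat <- make_long(matrix(5, 6, 3))
  r <- rm_anova_oneway(flat)
  expect_equal(r$F, 0)
  expect_equal(r$eta_sq, 0)
  set.seed(21)
  Y <- matrix(rnorm(16), 8, 2)
  r2 <- rm_anova_oneway(make_long(Y))
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p_uncorrected, tt$p.value, tolerance = 1e-10)
})

test_that("rmANOVA matches a brute-force sum-of-squares decomposition", {
  set.seed(22)
  Y <- matrix(rnorm(40, mean = rep(c(0, 1, 0.5, 2), each = 10)), 10, 4)
  d <- make_long(Y)
  r <- rm_anova_oneway(d)
  # direct SS oracle
  g <- mean(Y)
  ss_s <- 4 * sum((rowMeans(Y) - g)^2)
  ss_c <- 10 * sum((colMeans(Y) - g)^2)
  ss_t <- sum((Y - g)^2)
  ss_e <- ss_t - ss_s - ss_c
  expect_equal(unname(r$ss["total"]),
               unname(r$ss["subjects"] + r$ss["sessions"] + r$ss["error"]))
  expect_equal(unname(r$ss["sessions"]), ss_c)
  expect_equal(r$F, (ss_c / 3) / (ss_e / 27))
  expect_equal(r$eta_sq, ss_c / (ss_c + ss_e))
  expect_gt(r$gg_epsilon, 0)
  expect_lte(r$gg_epsilon, 1)
  expect_error(rm_anova_oneway(d[-1, ]), "unbalanced")
  expect_error(rm_anova_oneway(d[d$participant == 1, ]), "at least 2")
})

test_that("sum-of-squares conservation holds on random fixtures", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(5:12, 1); k <- sample(3:5, 1)
    Y <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k)
    r <- rm_anova_oneway(make_long(Y))
    expect_equal(unname(r$ss["total"]),
                 unname(sum(r$ss[c("subjects", "sessions", "error")])),
                 tolerance = 1e-9)
  }
})

test_that("Greenhouse-Geisser correction engages when sphericity fails", {
  set.seed(24)
  n <- 20
  base <- rnorm(n)
  # heavily correlated columns with unequal difference variances
  Y <- cbind(base, base + rnorm(n, sd = 0.1), base + rnorm(n, sd = 3),
             rnorm(n, sd = 0.5))
  r <- rm_anova_oneway(make_long(unname(Y)))
  expect_lt(r$mauchly_p, 0.05)
  expect_true(r$gg_applied)
  expect_equal(r$df, r$df_uncorrected * r$gg_epsilon)
  expect_gte(r$p, r$p_uncorrected)
})

test_that("Bonferroni contrasts multiply and cap p-values", {
  set.seed(25)
  Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  d <- make_long(Y)
  res <- paired_t_bonferroni(d)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_bonferroni >= res$p))
  expect_true(all(res$p_bonferroni <= 1))
  expect_equal(res$p_bonferroni, pmin(1, res$p * 3))
  one <- paired_t_bonferroni(d, contrasts = list(c("A", "B")))
  expect_equal(one$p_bonferroni, one$p)   # single contrast: identity
  # direct paired-t oracle
  dd <- Y[, "A"] - Y[, "B"]
  expect_equal(one$t, mean(dd) / (sd(dd) / sqrt(10)), tolerance = 1e-10)
  same <- make_long(cbind(A = Y[, 1], B = Y[, 1]))
  deg <- paired_t_bonferroni(same, contrasts = list(c("A", "B")))
  expect_true(deg$degenerate)
})

test_that("pooled-SD Cohen's d reproduces its closed form", {
  expect_equal(cohen_d_pooled(65.0, 22.8, 90.7, 23.4), 1.112, tolerance = 1e-3)
  expect_equal(cohen_d_pooled(90.7, 23.4, 106.3, 13.1), 0.823, tolerance = 1e-3)
  expect_equal(cohen_d_pooled(5, 1, 5, 2), 0)
  expect_error(cohen_d_pooled(1, 0, 2, 0), "undefined")
})

test_that("rm_corr is exact on within-participant linear data", {
  x <- rep(1:5, 4)
  offs <- rep(c(0, 10, 20, 30), each = 5)
  y <- -x + offs
  r <- rm_corr(x, y, rep(1:4, each = 5))
  expect_equal(r$r_rm, -1)
  expect_equal(r$df, 20 - 4 - 1)
  r2 <- rm_corr(x, x + offs, rep(1:4, each = 5))
  expect_equal(r2$r_rm, 1)
})

test_that("rm_corr on one participant reduces to Pearson", {
  set.seed(26)
  x <- rnorm(15); y <- 0.5 * x + rnorm(15)
  r <- rm_corr(x, y, rep(1, 15))
  expect_equal(r$r_rm, cor(x, y), tolerance = 1e-10)
  expect_equal(r$df, 13)
  ct <- cor.test(x, y)
  expect_equal(r$p, ct$p.value, tolerance = 1e-10)
})

test_that("rm_corr is near zero for unrelated data and drops constant-x participants", {
  set.seed(27)
  rs <- replicate(30, {
    x <- rnorm(40); y <- rnorm(40)
    rm_corr(x, y, rep(1:8, each = 5))$r_rm
  })
  expect_lt(abs(mean(rs)), 0.1)
  x <- c(rep(3, 5), rnorm(5))
  y <- rnorm(10)
  expect_warning(r <- rm_corr(x, y, rep(1:2, each = 5)), "constant x")
  expect_equal(r$dropped, "1")
})

test_that("chi-square matches its closed form exactly on integer tables", {
  r <- chi2_2x2(7, 22, 1, 22)
  closed <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  expect_equal(r$chi2, closed(7, 15, 1, 21), tolerance = 1e-12)
  expect_equal(r$chi2, 5.5, tolerance = 1e-12)
  expect_equal(round(r$fisher_p, 3), 0.046)
  expect_equal(chi2_2x2(0, 10, 0, 10)$chi2, 0)
  set.seed(28)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    expect_equal(chi2_2x2(k1, n1, k2, n2)$chi2,
                 closed(k1, n1 - k1, k2, n2 - k2), tolerance = 1e-10)
  }
})

test_that("Fisher two-sided p sums hypergeometric mass at most as likely", {
  # exact enumeration oracle for the 7/22 vs 1/22 table
  k_total <- 8; n1 <- 22; n2 <- 22
  probs <- dhyper(0:k_total, n1, n2, k_total)
  obs <- dhyper(7, n1, n2, k_total)
  oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
  expect_equal(chi2_2x2(7, 22, 1, 22)$fisher_p, oracle, tolerance = 1e-9)
})

test_that("jackknife correlation: zero bias on linear data, matches LOO loop", {
  x <- 1:10
  expect_equal(jackknife_corr(x, 2 * x + 3)$bias, 0)
  set.seed(29)
  a <- rnorm(12); b <- 0.6 * a + rnorm(12)
  jk <- jackknife_corr(a, b)
  loo <- vapply(1:12, function(i) cor(a[-i], b[-i]), numeric(1))
  expect_equal(jk$loo, loo)
  expect_equal(jk$r_jackknife, mean(loo))
  expect_equal(jk$bias, 11 * (mean(loo) - cor(a, b)))
  # an influential outlier widens the LOO spread
  a2 <- c(a, 10); b2 <- c(b, -10)
  expect_gt(diff(range(jackknife_corr(a2, b2)$loo)), diff(range(loo)))
  expect_error(jackknife_corr(rep(1, 5), rnorm(5)), "constant")
  expect_error(jackknife_corr(1:2, 1:2), "at least 3")
})

test_that("the mixed model finds an ipsilateral effect and not a contra one", {
  set.seed(30)
  n_p <- 12; n_t <- 30
  p <- rep(seq_len(n_p), each = n_t)
  ec <- rnorm(n_p * n_t, 20, 10)
  ei <- rnorm(n_p * n_t, 15, 15)
  ihi <- 100 + rep(rnorm(n_p, 0, 6), each = n_t) - 0.8 * ei +
    rnorm(n_p * n_t, 0, 5)
  m <- mixed_model_ihi(ihi, ec, ei, p)
  co <- m$coefficients
  expect_lt(co$p[co$term == "erd_ipsi"], 0.001)
  expect_gt(co$p[co$term == "erd_contra"], 0.05)
  expect_equal(co$estimate[co$term == "erd_ipsi"], -0.8, tolerance = 0.15)
  # zero-effect simulation: estimates near zero
  ihi0 <- 100 + rep(rnorm(n_p, 0, 6), each = n_t) + rnorm(n_p * n_t, 0, 5)
  m0 <- mixed_model_ihi(ihi0, ec, ei, p)
  expect_lt(max(abs(m0$coefficients$estimate[
    m0$coefficients$term %in% c("erd_contra", "erd_ipsi")])), 0.1)
  expect_warning(mixed_model_ihi(ihi, ec, ec, p), "collinear")
})

test_that("paired-t sample size search matches the noncentral-t oracle", {
  expect_lte(sample_size_paired_t(10), 3)
  # power is monotone in n
  pw <- vapply(2:20, function(n) erdtms:::paired_t_power(n, 0.8, 0.05),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  for (m in 1:3) {
    got <- sample_size_paired_t(0.82, 0.05, 0.8, m)
    oracle <- ceiling(power.t.test(delta = 0.82, sd = 1,
                                   sig.level = 0.05 / m, power = 0.8,
                                   type = "paired")$n)
    expect_equal(got, oracle)
  }
  # stricter correction can only demand more participants
  ns <- vapply(1:4, function(m) sample_size_paired_t(0.82, n_comparisons = m),
               integer(1))
  expect_true(all(diff(ns) >= 0))
  expect_error(sample_size_paired_t(-1), "positive")
})
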