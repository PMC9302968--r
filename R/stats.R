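#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Within-subject F test for a session factor on balanced complete data,
#' with partial eta squared, Mauchly's sphericity test, and a
#' Greenhouse-Geisser correction of the degrees of freedom applied when
#' Mauchly's test is significant (p < 0.05).
#'
#' @param data Data frame in long format: `participant`, `session`, `value`
#'   (one value per participant x session).
#' @return An object of class `rm_anova_result`: `F`, `df` (numerator,
#'   denominator; GG-corrected when applied), `p`, `eta_sq` (partial),
#'   `gg_epsilon`, `mauchly_p`, `gg_applied`, and the uncorrected
#'   `df_uncorrected` / `p_uncorrected`.
#' @export
rm_anova_oneway <- function(data) {
  data$participant <- factor(data$participant)
  data$session <- factor(data$session)
  k <- nlevels(data$session)
  n <- nlevels(data$participant)
  if (k < 2L || n < 2L) {
    stop("need at least 2 sessions and 2 participants", call. = FALSE)
  }
  tab <- table(data$participant, data$session)
  if (any(tab != 1L)) {
    stop("unbalanced data: exactly one value per participant x session; ",
         "use mixed_model_ihi() for unbalanced designs", call. = FALSE)
  }
  wide <- stats::reshape(data[order(data$participant, data$session),
                              c("participant", "session", "value")],
                         idvar = "participant", timevar = "session",
                         direction = "wide")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  grand <- mean(Y)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_sess <- n * sum((colMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_sess
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- if (ss_sess == 0) 0 else (ss_sess / df1) / (ss_err / df2)
  eta <- if (ss_sess == 0) 0 else ss_sess / (ss_sess + ss_err)
  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- stats::cov(Y)
  Sd <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- if (sum(Sd^2) == 0) 1 else sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
  mauchly_p <- if (k > 2L && n > k && sum(Sd^2) > 0) {
    fit <- stats::lm(Y ~ 1)
    stats::mauchly.test(fit, X = ~1)$p.value
  } else NA_real_   # sphericity is trivial with 2 levels / untestable small n
  gg <- !is.na(mauchly_p) && mauchly_p < 0.05
  df <- if (gg) c(df1 * eps, df2 * eps) else c(df1, df2)
  structure(
    list(F = Fv, df = df, p = stats::pf(Fv, df[1], df[2], lower.tail = FALSE),
         eta_sq = eta, gg_epsilon = eps, mauchly_p = mauchly_p,
         gg_applied = gg, df_uncorrected = c(df1, df2),
         p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
         ss = c(sessions = ss_sess, subjects = ss_subj, error = ss_err,
                total = ss_tot)),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("rmANOVA: F(%.2f, %.2f) = %.2f, p = %.4g, partial eta^2 = %.2f%s\n",
              x$df[1], x$df[2], x$F, x$p, x$eta_sq,
              if (x$gg_applied) " (Greenhouse-Geisser corrected)" else ""))
  invisible(x)
}

#' Post-hoc paired t-tests with Bonferroni correction
#'
#' Two-tailed paired t-tests for the requested session pairs; p-values are
#' multiplied by the number of contrasts and capped at 1.  Also reports the
#' paired-difference Cohen's d (mean difference over SD of differences).
#'
#' @param data Long-format data frame: `participant`, `session`, `value`.
#' @param contrasts List of length-2 character vectors of session pairs;
#'   default all pairs.
#' @return Data frame with `a`, `b`, `t`, `df`, `p`, `p_bonferroni`, `d`,
#'   and logical `degenerate` (zero variance of differences).
#' @export
paired_t_bonferroni <- function(data, contrasts = NULL) {
  data$session <- as.character(data$session)
  sessions <- unique(data$session)
  if (is.null(contrasts)) {
    contrasts <- utils::combn(sessions, 2, simplify = FALSE)
  }
  m <- length(contrasts)
  rows <- lapply(contrasts, function(ct) {
    stopifnot(all(ct %in% sessions))
    a <- data[data$session == ct[1], ]
    b <- data[data$session == ct[2], ]
    b <- b[match(a$participant, b$participant), ]
    d <- a$value - b$value
    if (stats::sd(d) == 0) {
      return(data.frame(a = ct[1], b = ct[2], t = NA_real_,
                        df = length(d) - 1, p = NA_real_,
                        p_bonferroni = NA_real_, d = NA_real_,
                        degenerate = TRUE))
    }
    tt <- stats::t.test(d)
    data.frame(a = ct[1], b = ct[2], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m),
               d = mean(d) / stats::sd(d), degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohen's d with pooled SD (two-group form)
#'
#' `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)` — the form used for a priori power
#' analysis from two group summaries.  For within-subject contrasts the
#' paired-difference form is reported by [paired_t_bonferroni()]; the two
#' do not coincide unless the correlation between conditions is 0.5.
#'
#' @param m1,s1 Mean and SD of the first group.
#' @param m2,s2 Mean and SD of the second group.
#' @return Cohen's d (>= 0).
#' @examples
#' cohen_d_pooled(65.0, 22.8, 90.7, 23.4)   # ~1.11
#' @export
cohen_d_pooled <- function(m1, s1, m2, s2) {
  if (s1 <= 0 || s2 <= 0) {
    if (s1 == 0 && s2 == 0) stop("undefined: both SDs are zero",
                                 call. = FALSE)
    stop("SDs must be positive", call. = FALSE)
  }
  abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2)
}

#' Repeated-measures (within-participant) correlation
#'
#' Common within-participant association between two variables measured
#' repeatedly in each participant: an analysis of covariance with
#' participant as a factor estimates the shared slope; r_rm is the signed
#' square root of the partial variance explained, with
#' df = N_obs - N_participants - 1.
#'
#' @param x,y Numeric vectors of paired observations.
#' @param participant Participant identifier, same length.
#' @return List with `r_rm`, `df`, `p`, `slope`, and `dropped` (participants
#'   removed for constant x).
#' @export
rm_corr <- function(x, y, participant) {
  participant <- factor(participant)
  keep <- rep(TRUE, length(x))
  dropped <- character(0)
  for (p in levels(participant)) {
    sel <- participant == p
    if (sum(sel) < 2L || stats::sd(x[sel]) == 0) {
      keep[sel] <- FALSE
      dropped <- c(dropped, p)
    }
  }
  if (length(dropped)) {
    warning("dropping participants with constant x: ",
            paste(dropped, collapse = ", "))
  }
  x <- x[keep]; y <- y[keep]; participant <- droplevels(participant[keep])
  if (nlevels(participant) < 1L) {
    stop("need at least 1 participant with varying x", call. = FALSE)
  }
  # a single participant degenerates to the ordinary Pearson correlation
  fit <- if (nlevels(participant) == 1L) stats::lm(y ~ x)
         else stats::lm(y ~ participant + x)
  # suppress the "essentially perfect fit" note on exact fixtures
  a <- suppressWarnings(stats::anova(fit))
  ss_x <- a["x", "Sum Sq"]
  ss_err <- a["Residuals", "Sum Sq"]
  slope <- stats::coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  df <- length(x) - nlevels(participant) - 1L
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(r_rm = r, df = df, p = p, slope = slope, dropped = dropped)
}

#' Chi-square and Fisher tests for two proportions
#'
#' Pearson chi-square on the 2x2 table without continuity correction (the
#' closed form `n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`), plus the two-sided
#' Fisher exact p obtained by summing the probabilities of all tables at
#' most as likely as the observed one.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return List with `chi2`, `p`, `fisher_p`.
#' @examples
#' chi2_2x2(7, 22, 1, 22)   # chi2 = 5.50
#' @export
chi2_2x2 <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    if (all(c(k1, k2) == 0) || all(c(k1, k2) == c(n1, n2))) {
      return(list(chi2 = 0, p = 1, fisher_p = 1))
    }
    stop("empty margin in the 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  ft <- stats::fisher.test(tab)
  list(chi2 = unname(ct$statistic), p = ct$p.value, fisher_p = ft$p.value)
}

#' Jackknife (leave-one-out) Pearson correlation with bias
#'
#' Leave-one-out Pearson correlations; the jackknife estimate is their
#' mean, and bias = (n - 1) * (mean LOO r - full-sample r).  Used to damp
#' the influence of single outlying observations on across-participant
#' correlations.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List with `r` (full-sample), `r_jackknife`, `bias`, and
#'   `loo` (the n leave-one-out coefficients).
#' @export
jackknife_corr <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined: constant series", call. = FALSE)
  }
  r_full <- stats::cor(x, y)
  loo <- vapply(seq_len(n), function(i) stats::cor(x[-i], y[-i]), numeric(1))
  r_jk <- mean(loo)
  list(r = r_full, r_jackknife = r_jk, bias = (n - 1) * (r_jk - r_full),
       loo = loo)
}

#' Linear mixed model of IHI on bilateral ERD
#'
#' Random-intercept model `ihi ~ erd_contra * erd_ipsi + (1 | participant)`
#' fitted with `lmerTest` (Satterthwaite p-values): per-trial IHI regressed
#' on the contralateral and ipsilateral ERD fixed effects plus their
#' interaction, with participant as a random effect.  On a singular fit the
#' function warns and falls back to participant-centered ordinary least
#' squares.
#'
#' @param ihi Per-observation IHI, percent.
#' @param erd_contra,erd_ipsi Per-observation ERD, percent.
#' @param participant Participant identifier.
#' @return List with `coefficients` (data frame: term, estimate, p),
#'   `singular`, and the fitted model in `fit`.
#' @export
mixed_model_ihi <- function(ihi, erd_contra, erd_ipsi, participant) {
  d <- data.frame(ihi = ihi, erd_contra = erd_contra, erd_ipsi = erd_ipsi,
                  participant = factor(participant))
  if (any(table(d$participant) < 2L)) {
    stop("need at least 2 observations per participant", call. = FALSE)
  }
  if (isTRUE(all.equal(erd_contra, erd_ipsi))) {
    warning("rank deficiency: contralateral and ipsilateral ERD are collinear")
  }
  fit <- suppressMessages(lmerTest::lmer(
    ihi ~ erd_contra * erd_ipsi + (1 | participant), data = d))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular mixed-model fit; falling back to participant-centered ",
            "regression")
    ols <- stats::lm(ihi ~ participant + erd_contra * erd_ipsi, data = d)
    sm <- summary(ols)$coefficients
    keep <- !grepl("^participant|Intercept", rownames(sm))
    co <- data.frame(term = rownames(sm)[keep],
                     estimate = sm[keep, "Estimate"],
                     p = sm[keep, "Pr(>|t|)"], row.names = NULL)
    return(list(coefficients = co, singular = TRUE, fit = ols))
  }
  sm <- stats::coef(summary(fit))
  keep <- rownames(sm) != "(Intercept)"
  co <- data.frame(term = rownames(sm)[keep],
                   estimate = sm[keep, "Estimate"],
                   p = sm[keep, "Pr(>|t|)"], row.names = NULL)
  list(coefficients = co, singular = FALSE, fit = fit)
}

# Power of a two-sided paired t-test at n pairs via the noncentral t.
paired_t_power <- function(n, d, alpha) {
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Sample size for a Bonferroni-corrected paired t-test
#'
#' Smallest number of pairs whose two-sided paired t-test at level
#' `alpha / n_comparisons` reaches the target power, by exact noncentral-t
#' search over n.
#'
#' @param d Effect size (paired-difference Cohen's d, > 0).
#' @param alpha Family-wise significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return Smallest sufficient n (integer, >= 2).
#' @export
sample_size_paired_t <- function(d, alpha = 0.05, power = 0.8,
                                 n_comparisons = 1L) {
  if (d <= 0) stop("effect size must be positive", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  a <- alpha / n_comparisons
  n <- 2L
  while (paired_t_power(n, d, a) < power) {
    n <- n + 1L
    if (n > 1e6L) stop("sample-size search did not converge", call. = FALSE)
  }
  n
}
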