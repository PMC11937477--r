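test_that("Shapiro-Wilk gate leaves normal samples and transforms skewed ones", {
  set.seed(106)
  norm_sample <- stats::rnorm(50)
  g1 <- shapiro_gate_transform(norm_sample + 10)
  expect_false(g1$transformed)
  skew_sample <- exp(stats::rnorm(50, sd = 1.5))
  g2 <- shapiro_gate_transform(skew_sample)
  expect_true(g2$transformed)
  expect_equal(unname(g2$summary["mean"]), exp(mean(log(skew_sample))))
  expect_error(shapiro_gate_transform(c(1, 2)), "at least 3")
  # gate fires but values include non-positives -> explicit error
  set.seed(102)
  bad <- c(exp(stats::rnorm(49, sd = 2)), -1)
  expect_error(shapiro_gate_transform(bad), "not all positive")
})

test_that("pooled t-test matches the closed-form oracle on summaries and raw data", {
  # closed-form pooled-t oracle, written independently of the implementation
  pooled_t <- function(n1, m1, s1, n2, m2, s2) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
  }
  cases <- list(
    list(a = list(n = 15, mean = 74, sd = 12), b = list(n = 15, mean = 49, sd = 14)),
    list(a = list(n = 5, mean = 10, sd = 1), b = list(n = 5, mean = 12, sd = 1)),
    list(a = list(n = 8, mean = 0.3, sd = 2.2), b = list(n = 20, mean = -1, sd = 1.4))
  )
  for (cs in cases) {
    got <- compare_groups_continuous(cs$a, cs$b)
    want <- pooled_t(cs$a$n, cs$a$mean, cs$a$sd, cs$b$n, cs$b$mean, cs$b$sd)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # the headline group difference: t about 5.25 and p below 0.001
  head <- compare_groups_continuous(list(n = 15, mean = 74, sd = 12),
                                    list(n = 15, mean = 49, sd = 14))
  expect_equal(head$t, 5.251, tolerance = 1e-3)
  expect_lt(head$p_value, 0.001)
  # raw-vector input agrees with t.test(var.equal = TRUE)
  set.seed(5)
  a <- stats::rnorm(12, 1); b <- stats::rnorm(17, 0)
  got <- compare_groups_continuous(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # identical groups
  same <- compare_groups_continuous(list(n = 10, mean = 5, sd = 2),
                                    list(n = 10, mean = 5, sd = 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # zero pooled variance with unequal means -> flagged p -> 0 limit
  deg <- compare_groups_continuous(list(n = 5, mean = 1, sd = 0),
                                   list(n = 5, mean = 2, sd = 0))
  expect_equal(deg$p_value, 0)
  expect_match(deg$flag, "zero pooled variance")
})

test_that("categorical comparison picks Fisher vs chi-square by expected counts", {
  # matched sex ratio: Fisher two-sided p = 1
  sex <- matrix(c(1, 1, 14, 14), 2)
  res <- compare_groups_categorical(sex)
  expect_equal(res$method, "fisher")
  expect_equal(res$p_value, 1)
  # perfect association
  res2 <- compare_groups_categorical(matrix(c(10, 0, 0, 10), 2))
  expect_lt(res2$p_value, 0.001)
  # exhaustive hypergeometric enumeration oracle for a 2x2 table
  fisher_brute <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    probs <- vapply(max(0, c1 - r2):min(r1, c1), function(a) {
      stats::dhyper(a, r1, r2, c1)
    }, numeric(1))
    p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tab <- matrix(c(14, 7, 1, 8), 2)
  res3 <- compare_groups_categorical(tab)
  expect_equal(res3$method, "fisher")
  expect_equal(res3$p_value, fisher_brute(tab), tolerance = 1e-10)
  # large balanced table -> chi-square path
  big <- matrix(c(30, 20, 25, 25), 2)
  res4 <- compare_groups_categorical(big)
  expect_equal(res4$method, "chi-square")
  expect_equal(res4$p_value,
               stats::chisq.test(big, correct = FALSE)$p.value)
  expect_error(compare_groups_categorical(matrix(c(0, 0, 3, 4), 2)),
               "empty margin")
})

test_that("Clopper-Pearson intervals reproduce printed bounds and behave", {
  ci_full <- clopper_pearson(15, 15)
  expect_equal(round(100 * ci_full[["lower"]]), 78)
  expect_equal(ci_full[["upper"]], 1)
  ci_12 <- clopper_pearson(12, 15)
  expect_equal(round(100 * ci_12[["lower"]]), 52)
  expect_equal(round(100 * ci_12[["upper"]]), 96)
  # closed-form boundary case: 0 of n
  n <- 15
  ci0 <- clopper_pearson(0, n)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - 0.025^(1 / n), tolerance = 1e-10)
  # the interval always contains the point estimate; width shrinks in n
  for (p in c(0.2, 0.5, 0.8)) {
    widths <- vapply(c(10, 40, 160, 640), function(n) {
      x <- round(p * n)
      ci <- clopper_pearson(x, n)
      expect_gte(x / n, ci[["lower"]])
      expect_lte(x / n, ci[["upper"]])
      ci[["upper"]] - ci[["lower"]]
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
  expect_error(clopper_pearson(5, 4), "counts")
})

test_that("ROC/Youden reports the paper-style operating point semantics", {
  # 15 positives all above 57, 12 of 15 negatives below it, high negatives
  # interleaved so the operating point is unique up to ties
  pos <- seq(58, 86, by = 2)
  neg <- c(seq(25, 47, by = 2), 60, 70, 80)
  r <- roc_youden(c(pos, neg), c(rep(TRUE, 15), rep(FALSE, 15)))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$youden_j, 0.8, tolerance = 1e-12)
  expect_equal(unname(round(100 * r$sensitivity_ci)), c(78, 100))
  expect_equal(unname(round(100 * r$specificity_ci)), c(52, 96))
  # perfectly separated scores
  r2 <- roc_youden(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(r2$auc, 1)
  expect_error(roc_youden(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    labels <- c(rep(TRUE, 5), rep(FALSE, 5),
                stats::runif(n - 10) > 0.5)
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # ties likely
    r <- roc_youden(scores, labels)
    xs <- scores[labels]; ys <- scores[!labels]
    cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- stats::rnorm(80)
  labels <- stats::runif(80) < stats::plogis(scores)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  r <- roc_youden(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("stepwise logistic selects the informative predictor and controls noise", {
  set.seed(77)
  n <- 2000
  x1 <- stats::rnorm(n, 60, 12)          # informative, OR 1.1 per unit
  noise <- matrix(stats::rnorm(n * 4), n)
  lp <- log(1.1) * (x1 - 60)
  y <- stats::rbinom(n, 1, stats::plogis(lp))
  df <- data.frame(y = y, x1 = x1, n1 = noise[, 1], n2 = noise[, 2],
                   n3 = noise[, 3], n4 = noise[, 4])
  fit <- stepwise_logistic(df, "y", c("x1", "n1", "n2", "n3", "n4"))
  expect_true("x1" %in% fit$selected)
  co <- fit$coefficients[fit$coefficients$term == "x1", ]
  expect_gt(1.1, co$or_lower)
  expect_lt(1.1, co$or_upper)
  # type-I control: with four independent noise candidates screened at
  # p-enter 0.05, the chance of an empty model is 0.95^4 = 0.815; the
  # simulated empty fraction must match that closed form
  set.seed(78)
  empty <- vapply(1:40, function(i) {
    d <- data.frame(y = stats::rbinom(500, 1, 0.4),
                    a = stats::rnorm(500), b = stats::rnorm(500),
                    c = stats::rnorm(500), d = stats::rnorm(500))
    length(stepwise_logistic(d, "y", c("a", "b", "c", "d"))$selected) == 0
  }, logical(1))
  p_empty <- 0.95^4
  se <- sqrt(p_empty * (1 - p_empty) / 40)
  expect_lt(abs(mean(empty) - p_empty), 3 * se)
  expect_error(stepwise_logistic(data.frame(y = rep(1, 20), x = 1:20),
                                 "y", "x"), "constant")
})

test_that("Pearson correlation handles the exact and degenerate cases", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_corr(x, x)$r, 1)
  set.seed(3)
  y <- -x + stats::rnorm(5, sd = 1e-9)
  expect_equal(pearson_corr(x, y)$r, -1, tolerance = 1e-6)
  ref <- stats::cor.test(x, c(2, 1, 5, 3, 9))
  got <- pearson_corr(x, c(2, 1, 5, 3, 9))
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_corr(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("absolute-agreement ICC matches the mean-squares oracle", {
  # oracle: mean squares from aov() fed into the ICC(A,1) formula
  icc_a1_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(seq_len(n), k)),
                    rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  m6 <- matrix(c(9, 6, 8, 7, 10, 6,
                 2, 1, 4, 1, 5, 2), ncol = 2)
  got <- icc_absolute(m6)
  expect_equal(got$icc, icc_a1_oracle(m6), tolerance = 1e-12)
  set.seed(10)
  m2 <- matrix(stats::rnorm(24, 50, 10), ncol = 3)
  expect_equal(icc_absolute(m2)$icc, icc_a1_oracle(m2), tolerance = 1e-12)
  # identical raters: perfect agreement
  base <- stats::rnorm(10, 60, 15)
  perfect <- icc_absolute(cbind(base, base))
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$label, "almost perfect")
  # high-agreement simulation lands in the top band
  set.seed(11)
  truth <- stats::rnorm(30, 60, 15)
  sim <- icc_absolute(cbind(truth + stats::rnorm(30, 0, 1.5),
                            truth + stats::rnorm(30, 0, 1.5)))
  expect_gte(sim$icc, 0.95)
  expect_equal(sim$label, "almost perfect")
  expect_error(icc_absolute(matrix(c(1, NA, 2, 3, 1, 2, 4, 5, 2, 9), 5)),
               "missing")
  expect_error(icc_absolute(matrix(1:6, 3)), "5 subjects")
})

test_that("Bland-Altman agreement matches the arithmetic oracle", {
  a <- c(4, 7, 1, 9)
  same <- bland_altman(a, a)
  expect_equal(same$mean_diff, 0)
  expect_equal(unname(same$loa), c(0, 0))
  # differences {1,-1,1,-1}
  b <- a - c(1, -1, 1, -1)
  ba <- bland_altman(a, b)
  sd_or <- stats::sd(c(1, -1, 1, -1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sd_or)
  expect_equal(unname(ba$loa), c(-1.96 * sd_or, 1.96 * sd_or))
  # constant offset, a - b convention
  off <- bland_altman(a, a + 2)
  expect_equal(off$mean_diff, -2)
  expect_equal(unname(off$loa), c(-2, -2))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("quartile ANOVA groups by inclusive quartiles with Tukey HSD", {
  # values 1..20 grouped by their own quartiles -> group means 3, 8, 13, 18
  q <- quartile_anova(1:20, 1:20)
  expect_equal(q$groups$mean, c(3, 8, 13, 18))
  expect_equal(q$groups$n, rep(5L, 4))
  # identical response distribution in all four groups -> F = 0, Tukey p = 1
  grouping <- 1:40
  response <- rep(c(2, 4, 6, 8, 10), 8)
  q0 <- quartile_anova(grouping, response)
  expect_lt(q0$f, 1e-20)
  expect_true(all(q0$tukey$p_adj > 0.999))
  # one clearly shifted quartile group is detected
  set.seed(21)
  g <- 1:40
  r <- stats::rnorm(40) + 3 * (g > 30)
  q1 <- quartile_anova(g, r)
  expect_lt(q1$p_value, 0.001)
  q4_rows <- grepl("Q4", q1$tukey$contrast)
  expect_true(all(q1$tukey$p_adj[q4_rows] < 0.05))
  expect_error(quartile_anova(rep(1, 20), stats::rnorm(20)), "ties")
})

test_that("tidy and glance methods return well-formed tibbles", {
  set.seed(14)
  r <- roc_youden(stats::rnorm(40), rep(c(TRUE, FALSE), 20))
  expect_s3_class(generics::tidy(r), "tbl_df")
  gl <- generics::glance(r)
  expect_named(gl, c("auc", "auc_lower", "auc_upper", "cutoff",
                     "sensitivity", "sensitivity_lower", "sensitivity_upper",
                     "specificity", "specificity_lower", "specificity_upper",
                     "youden_j", "n_pos", "n_neg"))
  ba <- bland_altman(stats::rnorm(10), stats::rnorm(10))
  expect_equal(nrow(generics::tidy(ba)), 10)
  expect_equal(nrow(generics::glance(ba)), 1)
})
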