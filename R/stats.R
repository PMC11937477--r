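# The statistical battery applied to cohort tables: Shapiro-Wilk gated
# transforms, Student's t (raw or summary-statistic input), chi-square /
# Fisher, ROC with the Youden cutoff and exact binomial CIs, stepwise
# logistic regression, Pearson correlation, absolute-agreement ICC,
# Bland-Altman, and quartile ANOVA with Tukey HSD.

#' Shapiro-Wilk gated log transform
#'
#' Tests normality of the raw values; when rejected (p < `alpha`) the values
#' are natural-log transformed and summaries are reported as geometric mean
#' and geometric SD on back-transform.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha rejection level for the normality gate.
#' @return A list: `values` (possibly transformed), `transformed` flag,
#'   `shapiro_p`, and `summary` (mean/SD — geometric if transformed).
#' @export
shapiro_gate_transform <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop("need at least 3 finite values for the normality gate", call. = FALSE)
  }
  p <- stats::shapiro.test(values)$p.value
  transformed <- p < alpha
  if (transformed) {
    if (any(values <= 0)) {
      stop("log transform required by the normality gate but values are ",
           "not all positive", call. = FALSE)
    }
    lv <- log(values)
    summ <- c(mean = exp(mean(lv)), sd = exp(stats::sd(lv)))
    out <- lv
  } else {
    summ <- c(mean = mean(values), sd = stats::sd(values))
    out <- values
  }
  list(values = out, transformed = transformed, shapiro_p = p,
       summary = summ)
}

#' Two-group comparison of a continuous variable (Student's t)
#'
#' Pooled-variance two-sample Student's t-test, two-sided. Accepts either
#' raw per-group vectors (optionally Shapiro-gated log transform first) or
#' summary statistics (n, mean, SD per group), so printed group summaries
#' can be tested directly.
#'
#' @param a,b numeric vectors, or lists `list(n =, mean =, sd =)`.
#' @param gate apply [shapiro_gate_transform()] to the pooled raw values
#'   before testing (ignored for summary input).
#' @return A `brw_group_comparison` list: per-group n/mean/sd, `t`, `df`,
#'   `p_value`, `transformed`.
#' @export
compare_groups_continuous <- function(a, b, gate = FALSE) {
  summarise_input <- function(x) {
    if (is.list(x) && all(c("n", "mean", "sd") %in% names(x))) {
      c(n = x$n, mean = x$mean, sd = x$sd)
    } else {
      x <- x[is.finite(x)]
      c(n = length(x), mean = mean(x), sd = stats::sd(x))
    }
  }
  transformed <- FALSE
  if (gate && is.numeric(a) && is.numeric(b)) {
    g <- shapiro_gate_transform(c(a, b))
    transformed <- g$transformed
    if (transformed) { a <- log(a); b <- log(b) }
  }
  sa <- summarise_input(a); sb <- summarise_input(b)
  if (sa[["n"]] < 2 || sb[["n"]] < 2) {
    stop("need n >= 2 per group", call. = FALSE)
  }
  df <- sa[["n"]] + sb[["n"]] - 2
  sp2 <- ((sa[["n"]] - 1) * sa[["sd"]]^2 + (sb[["n"]] - 1) * sb[["sd"]]^2) / df
  delta <- sa[["mean"]] - sb[["mean"]]
  flag <- NULL
  if (sp2 == 0) {
    if (delta == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(delta) * Inf; p <- 0
      flag <- "zero pooled variance with unequal means: p reported as the limit 0"
    }
  } else {
    se <- sqrt(sp2 * (1 / sa[["n"]] + 1 / sb[["n"]]))
    tstat <- delta / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(
    group_a = sa, group_b = sb, t = tstat, df = df, p_value = p,
    transformed = transformed, flag = flag
  ), class = "brw_group_comparison")
}

#' Two-group comparison of a categorical variable
#'
#' Fisher's exact test (two-sided) when any expected cell count is below 5,
#' otherwise the chi-square test without continuity correction.
#'
#' @param tab 2x2 (or r x c) matrix of non-negative integer counts.
#' @return A list: `method`, `p_value`, `statistic` (chi-square only),
#'   `expected`.
#' @export
compare_groups_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    list(method = "fisher", p_value = ft$p.value, statistic = NA_real_,
         expected = expected)
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(method = "chi-square", p_value = ct$p.value,
         statistic = unname(ct$statistic), expected = expected)
  }
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form with the closed-form boundary cases.
#'
#' @param successes number of successes, `0 <= successes <= n`.
#' @param n number of trials, >= 1.
#' @param level confidence level.
#' @return `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stop("need integer counts with 0 <= successes <= n and n >= 1",
         call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' ROC analysis with the Youden-index operating point
#'
#' Builds the empirical ROC curve, computes the AUC by the trapezoidal rule
#' (equivalent to the normalized Mann-Whitney U statistic), selects the
#' cutoff maximizing Youden's J = sensitivity + specificity - 1 (ties broken
#' toward the lowest cutoff, favouring sensitivity), and attaches exact
#' Clopper-Pearson CIs for sensitivity and specificity at that cutoff and a
#' DeLong-variance CI for the AUC.
#'
#' @param scores numeric biomarker values (higher = more likely positive).
#' @param labels logical or 0/1 vector; `TRUE`/1 is the positive class.
#' @param level confidence level for the CIs.
#' @return A `brw_roc` list: `auc`, `auc_ci`, `cutoff`, `sensitivity`,
#'   `specificity` with CIs, `youden_j`, and the full `curve` tibble
#'   (cutoff, FPR, TPR).
#' @export
roc_youden <- function(scores, labels, level = 0.95) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  # candidate cutoffs: classify positive if score >= cutoff
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(c) mean(scores[labels] >= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(scores[!labels] < c), numeric(1))
  curve <- tibble::tibble(
    cutoff = c(-Inf, cuts, Inf),
    tpr = c(1, sens, 0),
    fpr = c(1, 1 - spec, 0)
  )
  # trapezoidal AUC over the empirical curve
  o <- order(curve$fpr, curve$tpr)
  fx <- curve$fpr[o]; fy <- curve$tpr[o]
  auc <- sum(diff(fx) * (fy[-1] + fy[-length(fy)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]   # lowest cutoff at ties
  se_ci <- clopper_pearson(round(sens[best] * n_pos), n_pos, level)
  sp_ci <- clopper_pearson(round(spec[best] * n_neg), n_neg, level)
  auc_ci <- delong_auc_ci(scores, labels, auc, level)
  structure(list(
    auc = auc, auc_ci = auc_ci, cutoff = cuts[best],
    sensitivity = sens[best], sensitivity_ci = se_ci,
    specificity = spec[best], specificity_ci = sp_ci,
    youden_j = j[best], n_pos = n_pos, n_neg = n_neg, curve = curve
  ), class = "brw_roc")
}

# DeLong placement-value variance for the AUC; CI clamped to [0, 1].
delong_auc_ci <- function(scores, labels, auc, level = 0.95) {
  xs <- scores[labels]; ys <- scores[!labels]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) mean(x > ys) + 0.5 * mean(x == ys), numeric(1))
  v01 <- vapply(ys, function(y) mean(xs > y) + 0.5 * mean(xs == y), numeric(1))
  s2 <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * sqrt(s2)), upper = min(1, auc + z * sqrt(s2)))
}

#' @export
print.brw_roc <- function(x, ...) {
  cat(sprintf("<brw_roc> AUC = %.3f (%.2f-%.2f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Youden cutoff %.3g: sensitivity %.0f%% (%.0f-%.0f%%), specificity %.0f%% (%.0f-%.0f%%), J = %.2f\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2], 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2],
              x$youden_j))
  invisible(x)
}

#' Stepwise logistic regression (forward p-enter / backward p-remove)
#'
#' Forward selection adds, at each step, the candidate whose
#' likelihood-ratio p-value is smallest and below `p_enter`; backward
#' elimination then removes terms whose p-value exceeds `p_remove`, until
#' stable. Odds ratios are `exp(coef)` with Wald CIs. Complete separation is
#' flagged and a weakly ridge-penalized refit is reported alongside.
#'
#' @param data data frame.
#' @param outcome name of the binary outcome column.
#' @param predictors character vector of candidate predictor columns.
#' @param p_enter,p_remove forward/backward p-value thresholds.
#' @return A `brw_stepwise` list: `selected`, `coefficients` tibble
#'   (term, estimate, odds ratio + CI, p), `separation` flag, `model`.
#' @export
stepwise_logistic <- function(data, outcome, predictors,
                              p_enter = 0.05, p_remove = 0.10) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome is constant: both classes required", call. = FALSE)
  }
  if (nrow(data) <= length(predictors)) {
    stop("need more observations than candidate predictors", call. = FALSE)
  }
  df <- data
  df[[outcome]] <- y
  current <- character(0)
  fit_formula <- function(terms) {
    f <- stats::as.formula(paste(
      outcome, "~", if (length(terms) == 0) "1" else paste(terms, collapse = "+")))
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = df))
  }
  fit <- fit_formula(current)
  repeat {
    # forward step: best LRT p among remaining candidates
    remaining <- setdiff(predictors, current)
    added <- FALSE
    if (length(remaining) > 0) {
      ps <- vapply(remaining, function(v) {
        f2 <- fit_formula(c(current, v))
        stats::pchisq(fit$deviance - f2$deviance, df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (min(ps) < p_enter) {
        current <- c(current, remaining[which.min(ps)])
        fit <- fit_formula(current)
        added <- TRUE
      }
    }
    # backward step: drop worst term above p_remove
    removed <- FALSE
    while (length(current) > 0) {
      ps <- vapply(current, function(v) {
        f0 <- fit_formula(setdiff(current, v))
        stats::pchisq(f0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (max(ps) > p_remove) {
        current <- setdiff(current, current[which.max(ps)])
        fit <- fit_formula(current)
        removed <- TRUE
      } else break
    }
    if (!added && !removed) break
  }
  separation <- any(fit$fitted.values > 1 - 1e-8) &&
    any(fit$fitted.values < 1e-8) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  co <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = co[, 1],
    std_error = co[, 2],
    odds_ratio = exp(co[, 1]),
    or_lower = exp(co[, 1] - z * co[, 2]),
    or_upper = exp(co[, 1] + z * co[, 2]),
    p_value = co[, 4]
  )
  penalized <- NULL
  if (isTRUE(separation) && length(current) > 0) {
    # weak ridge penalty stabilizes the separated fit
    X <- as.matrix(df[, current, drop = FALSE])
    gl <- glmnet_safe(X, y)
    if (!is.null(gl)) penalized <- gl
  }
  structure(list(
    selected = current, coefficients = coefs, separation = separation,
    penalized = penalized, model = fit
  ), class = "brw_stepwise")
}

glmnet_safe <- function(X, y) {
  if (!requireNamespace("glmnet", quietly = TRUE)) return(NULL)
  if (ncol(X) < 2) X <- cbind(X, 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 1e-3)
  b <- as.numeric(stats::coef(fit))
  tibble::tibble(term = rownames(stats::coef(fit)), estimate = b,
                 odds_ratio = exp(b))
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors, equal length, n >= 3.
#' @return A list: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

icc_band_label <- function(icc) {
  if (icc <= 0) "null"
  else if (icc < 0.20) "slight"
  else if (icc < 0.40) "fair"
  else if (icc < 0.60) "moderate"
  else if (icc < 0.80) "good"
  else if (icc < 0.95) "very good"
  else "almost perfect"
}

#' Absolute-agreement intraclass correlation (two-way mixed, single measure)
#'
#' ICC(A,1) from the two-way ANOVA mean squares, with the F-distribution
#' confidence bounds and the categorical agreement label
#' (null / slight / fair / moderate / good / very good / almost perfect,
#' the last being ICC >= 0.95).
#'
#' @param readings numeric matrix, subjects x raters, no missing cells.
#' @param level confidence level.
#' @return A `brw_icc` list: `icc`, `ci`, `label`, mean squares.
#' @export
icc_absolute <- function(readings, level = 0.95) {
  m <- as.matrix(readings)
  if (anyNA(m)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (k < 2 || n < 5) {
    stop("need at least 2 raters and 5 subjects", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong F-based bounds for ICC(A,1)
  alpha <- 1 - level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(
    icc = icc, ci = c(lower = lower, upper = upper),
    label = icc_band_label(icc),
    ms = c(rows = msr, cols = msc, error = mse), n = n, k = k
  ), class = "brw_icc")
}

#' @export
print.brw_icc <- function(x, ...) {
  cat(sprintf("<brw_icc> ICC(A,1) = %.3f (%.3f-%.3f), %s\n",
              x$icc, x$ci[1], x$ci[2], x$label))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Mean paired difference (a - b) with its t-based 95% CI and the limits of
#' agreement, mean difference +/- 1.96 SD of the differences.
#'
#' @param a,b paired numeric vectors, equal length, n >= 2.
#' @return A `brw_bland_altman` list: `mean_diff`, `ci`, `loa`, `sd_diff`,
#'   and the per-pair `table` (mean, difference).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length",
                                   call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  se <- sdd / sqrt(n)
  tq <- stats::qt(0.975, n - 1)
  structure(list(
    mean_diff = md, ci = c(lower = md - tq * se, upper = md + tq * se),
    sd_diff = sdd, loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
    n = n, table = tibble::tibble(mean = (a + b) / 2, diff = d)
  ), class = "brw_bland_altman")
}

#' Quartile-group ANOVA with Tukey HSD
#'
#' Groups observations by the quartiles of a grouping biomarker (inclusive
#' linear interpolation of order statistics; boundary values fall in the
#' lower group) and compares a response across the four groups with one-way
#' ANOVA and all-pairs Tukey HSD.
#'
#' @param grouping numeric biomarker used to form quartile groups.
#' @param response numeric response compared across the groups.
#' @return A `brw_quartile_anova` list: `f`, `p_value`, `groups` summary
#'   tibble, `tukey` tibble of adjusted pairwise p-values.
#' @export
quartile_anova <- function(grouping, response) {
  ok <- is.finite(grouping) & is.finite(response)
  grouping <- grouping[ok]; response <- response[ok]
  if (length(grouping) < 8) stop("need n >= 8", call. = FALSE)
  q <- stats::quantile(grouping, c(0.25, 0.5, 0.75), type = 7)
  if (any(duplicated(q))) {
    stop("quartile group empty: massive ties in the grouping variable (",
         paste(format(q, digits = 4), collapse = ", "), ")", call. = FALSE)
  }
  grp <- cut(grouping, breaks = c(-Inf, q, Inf),
             labels = paste0("Q", 1:4), right = TRUE)
  if (any(table(grp) == 0)) {
    stop("quartile group empty: massive ties in the grouping variable",
         call. = FALSE)
  }
  fit <- stats::aov(response ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  structure(list(
    f = an[1, "F value"], p_value = an[1, "Pr(>F)"],
    groups = tibble::tibble(
      group = levels(grp),
      n = as.integer(table(grp)),
      mean = as.numeric(tapply(response, grp, mean)),
      sd = as.numeric(tapply(response, grp, stats::sd))
    ),
    tukey = tibble::tibble(
      contrast = rownames(tk),
      diff = tk[, "diff"], lower = tk[, "lwr"], upper = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  ), class = "brw_quartile_anova")
}
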