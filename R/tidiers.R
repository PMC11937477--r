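# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.brw_roc <- function(x, ...) {
  x$curve
}

#' @export
glance.brw_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_lower = x$auc_ci[[1]], auc_upper = x$auc_ci[[2]],
    cutoff = x$cutoff, sensitivity = x$sensitivity,
    sensitivity_lower = x$sensitivity_ci[[1]],
    sensitivity_upper = x$sensitivity_ci[[2]],
    specificity = x$specificity,
    specificity_lower = x$specificity_ci[[1]],
    specificity_upper = x$specificity_ci[[2]],
    youden_j = x$youden_j, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @export
tidy.brw_group_comparison <- function(x, ...) {
  tibble::tibble(
    group = c("a", "b"),
    n = c(x$group_a[["n"]], x$group_b[["n"]]),
    mean = c(x$group_a[["mean"]], x$group_b[["mean"]]),
    sd = c(x$group_a[["sd"]], x$group_b[["sd"]])
  )
}

#' @export
glance.brw_group_comparison <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p_value = x$p_value,
                 transformed = x$transformed)
}

#' @export
tidy.brw_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, lower = x$ci[[1]], upper = x$ci[[2]],
                 label = x$label, n_subjects = x$n, n_raters = x$k)
}

#' @export
tidy.brw_bland_altman <- function(x, ...) {
  x$table
}

#' @export
glance.brw_bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$mean_diff, ci_lower = x$ci[[1]], ci_upper = x$ci[[2]],
    sd_diff = x$sd_diff, loa_lower = x$loa[[1]], loa_upper = x$loa[[2]],
    n = x$n
  )
}

#' @export
tidy.brw_stepwise <- function(x, ...) {
  x$coefficients
}

#' @export
glance.brw_stepwise <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    selected = paste(x$selected, collapse = ","),
    separation = x$separation,
    deviance = x$model$deviance, aic = x$model$aic
  )
}

#' @export
tidy.brw_quartile_anova <- function(x, ...) {
  x$tukey
}

#' @export
glance.brw_quartile_anova <- function(x, ...) {
  tibble::tibble(f = x$f, p_value = x$p_value)
}

#' @export
tidy.wall_measurement <- function(x, ...) {
  tibble::tibble(LA = x$LA, WA = x$WA, WA_percent = x$WA_percent,
                 status = x$status, sigma_mm = x$sigma_mm,
                 fail_frac = x$fail_frac)
}

#' @export
tidy.patient_biomarkers <- function(x, ...) {
  x$per_path
}

#' @export
glance.patient_biomarkers <- function(x, ...) {
  tibble::tibble(brwall_t2_mis = x$brwall_t2_mis,
                 n_paths = nrow(x$per_path),
                 n_excluded = nrow(x$excluded))
}
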