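#' Cohort specification
#'
#' Parameters of the synthetic two-group asthma cohort: per-group sample
#' size, group means/SDs of the bronchial-wall T2 biomarker
#' (BrWall_T2-MIS), whole-cohort (pooled) target Pearson correlations
#' between the biomarker and the clinical covariates, the
#' exacerbation-risk model, and the reader measurement-error level used for
#' the reproducibility replicates.
#'
#' Correlation targets are *pooled* over both groups, matching how
#' whole-cohort correlations are reported clinically: the generator solves
#' for the within-group covariance that, combined with the group mean
#' separation, yields the requested pooled correlation.
#'
#' @param n_per_group patients per severity group.
#' @param brwall_mean,brwall_sd named (`non_severe`, `severe`) group mean and
#'   SD of BrWall_T2-MIS in arbitrary units.
#' @param correlations named vector of pooled Pearson targets between
#'   BrWall_T2-MIS and covariates; names among
#'   `fev1_pct_pred`, `fvc_pct_pred`, `fev1_fvc`, `fef2575_pct_pred`,
#'   `pef_l_min`, `log_feno`, `log_eos`, `wa_percent`.
#' @param or_aer_per_au odds ratio per arbitrary unit of BrWall_T2-MIS for
#'   a frequent-exacerbator outcome (two or more exacerbations in the next
#'   12 months).
#' @param aer_anchor biomarker value at which the frequent-exacerbator
#'   probability is 50%.
#' @param reader_sd SD of the per-reading measurement error used to build
#'   intra/inter-reader replicates.
#' @param seed integer seed; fully determines the table.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 15,
                        brwall_mean = c(non_severe = 49, severe = 74),
                        brwall_sd = c(non_severe = 14, severe = 12),
                        correlations = c(fev1_pct_pred = -0.54,
                                         fvc_pct_pred = -0.46,
                                         fev1_fvc = -0.44,
                                         fef2575_pct_pred = -0.49,
                                         pef_l_min = -0.37,
                                         log_feno = 0.06,
                                         log_eos = 0.36,
                                         wa_percent = 0.25),
                        or_aer_per_au = 1.11,
                        aer_anchor = 62,
                        reader_sd = 0.7,
                        seed = 1L) {
  structure(list(
    n_per_group = as.integer(n_per_group),
    brwall_mean = brwall_mean, brwall_sd = brwall_sd,
    correlations = correlations,
    or_aer_per_au = or_aer_per_au, aer_anchor = aer_anchor,
    reader_sd = reader_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Covariate group means/SDs on the latent (possibly log) scale.
cohort_covariate_table <- function() {
  tibble::tribble(
    ~var,                ~mean_ns,  ~sd_ns,    ~mean_sev,  ~sd_sev,
    "fev1_pct_pred",     101,       18,        80,         26,
    "fvc_pct_pred",      108,       15,        94,         21,
    "fev1_fvc",          0.75,      0.08,      0.65,       0.10,
    "fef2575_pct_pred",  83,        34,        51,         36,
    "pef_l_min",         418,       106,       314,        116,
    "log_feno",          log(21),   log(1.5),  log(21),    log(1.6),
    "log_eos",           log(128),  log(2),    log(165),   log(3),
    "wa_percent",        71,        5,         74,         4
  )
}

# Plausible within-group correlations among the covariates themselves
# (spirometric indices co-vary; type-2 markers co-vary weakly).
cohort_base_correlation <- function(vars) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("fev1_pct_pred", "fvc_pct_pred", 0.70)
  set_r("fev1_pct_pred", "fev1_fvc", 0.60)
  set_r("fev1_pct_pred", "fef2575_pct_pred", 0.70)
  set_r("fev1_pct_pred", "pef_l_min", 0.60)
  set_r("fvc_pct_pred", "pef_l_min", 0.50)
  set_r("fvc_pct_pred", "fef2575_pct_pred", 0.40)
  set_r("fvc_pct_pred", "fev1_fvc", 0.10)
  set_r("fef2575_pct_pred", "fev1_fvc", 0.60)
  set_r("fef2575_pct_pred", "pef_l_min", 0.50)
  set_r("pef_l_min", "fev1_fvc", 0.30)
  set_r("log_feno", "log_eos", 0.30)
  set_r("wa_percent", "fev1_pct_pred", -0.30)
  set_r("wa_percent", "fev1_fvc", -0.30)
  set_r("wa_percent", "fef2575_pct_pred", -0.20)
  R
}

# Solve for the within-group correlation between the biomarker and each
# covariate that produces the requested pooled correlation, given the group
# mean separations (two equally sized groups).
pooled_to_within_corr <- function(spec, cov_tab) {
  db <- spec$brwall_mean[["severe"]] - spec$brwall_mean[["non_severe"]]
  var_b_w <- mean(spec$brwall_sd^2)
  sd_b_pool <- sqrt(var_b_w + db^2 / 4)
  out <- numeric(nrow(cov_tab))
  names(out) <- cov_tab$var
  for (i in seq_len(nrow(cov_tab))) {
    v <- cov_tab$var[i]
    rt <- spec$correlations[[v]]
    if (is.null(rt) || is.na(rt)) { out[i] <- 0; next }
    dv <- cov_tab$mean_sev[i] - cov_tab$mean_ns[i]
    sd_v_pool <- sqrt(mean(c(cov_tab$sd_ns[i]^2, cov_tab$sd_sev[i]^2)) +
                        dv^2 / 4)
    mean_cross_sd <- mean(c(spec$brwall_sd[["non_severe"]] * cov_tab$sd_ns[i],
                            spec$brwall_sd[["severe"]] * cov_tab$sd_sev[i]))
    rho <- (rt * sd_b_pool * sd_v_pool - db * dv / 4) / mean_cross_sd
    if (abs(rho) >= 1) {
      stop(sprintf(paste0("pooled correlation target %.2f for '%s' is not ",
                          "attainable with the given group separations"),
                   rt, v), call. = FALSE)
    }
    out[i] <- rho
  }
  out
}

#' Generate a synthetic two-group cohort table
#'
#' Draws per-group multivariate-normal latent covariates calibrated so the
#' pooled Pearson correlations with BrWall_T2-MIS converge to the targets,
#' back-transforms the log-scale biomarkers (FeNO, blood eosinophils),
#' simulates the frequent-exacerbator outcome from a logistic model in the
#' biomarker, and adds intra/inter-reader replicate readings.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with one row per patient: `patient_id`, `group`,
#'   `severe`, `brwall_t2_mis` (reader-1 reading), replicate readings
#'   (`brwall_reader1b`, `brwall_reader2`), `wa_percent`, spirometry
#'   (`fev1_pct_pred`, `fvc_pct_pred`, `fev1_fvc`, `fef2575_pct_pred`,
#'   `pef_l_min`), `feno_ppb`, `eos_cells_ul`, `exac_next12`, `aer_ge2`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cov_tab <- cohort_covariate_table()
  vars <- c("brwall", cov_tab$var)
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  R[cov_tab$var, cov_tab$var] <- cohort_base_correlation(cov_tab$var)
  rho_b <- pooled_to_within_corr(spec, cov_tab)
  R["brwall", cov_tab$var] <- rho_b
  R[cov_tab$var, "brwall"] <- rho_b
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied within-group correlation matrix is not positive ",
         "semi-definite", call. = FALSE)
  }

  draw_group <- function(group) {
    g <- if (group == "severe") "severe" else "non_severe"
    mu <- c(spec$brwall_mean[[g]],
            if (g == "severe") cov_tab$mean_sev else cov_tab$mean_ns)
    sd <- c(spec$brwall_sd[[g]],
            if (g == "severe") cov_tab$sd_sev else cov_tab$sd_ns)
    Sigma <- diag(sd) %*% R %*% diag(sd)
    X <- MASS::mvrnorm(spec$n_per_group, mu = mu, Sigma = Sigma)
    colnames(X) <- vars
    tibble::as_tibble(X) |>
      dplyr::mutate(group = group, .before = 1)
  }
  tab <- dplyr::bind_rows(draw_group("non-severe"), draw_group("severe"))

  n <- nrow(tab)
  b1 <- log(spec$or_aer_per_au)
  p_aer <- stats::plogis(b1 * (tab$brwall - spec$aer_anchor))
  aer_ge2 <- stats::rbinom(n, 1, p_aer) == 1
  exac <- ifelse(aer_ge2,
                 2L + stats::rpois(n, 1.2),
                 stats::rbinom(n, 1, 0.2))

  tab |>
    dplyr::mutate(
      patient_id = sprintf("P%03d", dplyr::row_number()), .before = 1
    ) |>
    dplyr::mutate(
      severe = .data$group == "severe",
      brwall_true = .data$brwall,
      brwall_t2_mis = .data$brwall + stats::rnorm(n, 0, spec$reader_sd),
      brwall_reader1b = .data$brwall + stats::rnorm(n, 0, spec$reader_sd),
      brwall_reader2 = .data$brwall + stats::rnorm(n, 0, spec$reader_sd),
      feno_ppb = exp(.data$log_feno),
      eos_cells_ul = exp(.data$log_eos),
      exac_next12 = exac,
      aer_ge2 = aer_ge2
    ) |>
    dplyr::select("patient_id", "group", "severe", "brwall_t2_mis",
                  "brwall_true", "brwall_reader1b", "brwall_reader2",
                  "wa_percent", "fev1_pct_pred", "fvc_pct_pred", "fev1_fvc",
                  "fef2575_pct_pred", "pef_l_min", "feno_ppb",
                  "eos_cells_ul", "exac_next12", "aer_ge2")
}
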