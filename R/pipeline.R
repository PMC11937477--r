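# End-to-end orchestration: phantom generation -> T2w normalization ->
# registration to the UTE-like frame -> airway tree extraction -> wall
# measurement -> biomarker table -> statistics, with a per-run manifest
# (stage status, checksums, exclusions, seed, config hash).

#' Default run configuration
#'
#' Every module parameter has a default; a YAML file with the same nesting
#' can override any subset (see [load_config()]). The config hash is logged
#' in every manifest.
#'
#' @return A nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cohort_mode = "phantom",   # phantom | volumes | table-only
    n_per_group = 15L,
    phantom = list(
      grid_shape = c(96L, 96L, 96L),
      voxel_size_mm = 1.0,
      tree_depth = 3L,
      deformation = list(amplitude_mm = 3, period_mm = 48),
      wall_signal_mean = c(non_severe = 49, severe = 74),
      wall_signal_sd = c(non_severe = 14, severe = 12)
    ),
    register = list(levels = 4L, max_iter = c(60L, 45L, 18L, 0L),
                    tol = 1e-4, sigma_diffusion = 1.6, sigma_fluid = 4.0,
                    presmooth_vox = 1.0, step = 2.0),
    airway = list(lumen_threshold = -500, prune_mm = 4),
    measure = list(sigma_sweep = c(0.3, 0.5, 0.8), n_rays = 64L,
                   n_sites = 2L, slab_half_mm = 1, half_size_mm = 8),
    qc = list(alignment_threshold = 0.8),
    output_dir = NULL
  )
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it (recursively) over [default_config()],
#' so a config file only states what it changes.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return The merged config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_hash <- function(config) digest::digest(config, algo = "sha256")

new_manifest <- function(config, seed) {
  env <- new.env()
  env$stages <- list()
  env$checksums <- list()
  env$exclusions <- list()
  env$config_hash <- config_hash(config)
  env$seed <- seed
  env
}

log_stage <- function(man, stage, status, detail = "") {
  man$stages[[length(man$stages) + 1]] <- tibble::tibble(
    stage = stage, status = status, detail = detail)
  invisible(man)
}

manifest_tibble <- function(man) {
  list(
    stages = dplyr::bind_rows(man$stages),
    checksums = man$checksums,
    exclusions = dplyr::bind_rows(man$exclusions),
    config_hash = man$config_hash,
    seed = man$seed
  )
}

#' Run the full measurement pipeline for one subject
#'
#' Executes, in order: T2w normalization (on the native T2w volume),
#' registration of the CT-like and T2w-like volumes onto the UTE-like
#' reference, lumen segmentation and centerline tree extraction on the
#' registered CT, lobar path selection with mucus exclusion, two
#' cross-sectional wall measurements per path, wall-mask transfer onto the
#' normalized registered T2w, and the per-patient biomarkers. Per-path
#' failures are isolated as exclusion records, not run failures.
#'
#' @param config a config list (see [default_config()]).
#' @param subject_id identifier used in outputs.
#' @param phantom a [generate_phantom()] result; alternatively supply
#'   `volumes` for real data.
#' @param volumes optional list `ct`, `ute`, `t2w` of [brw_volume()]s plus
#'   `seed_mm` (tracheal seed) and `lobe_map` when not using a phantom.
#' @return A list: `biomarkers` (one-row tibble: subject, BrWall_T2-MIS,
#'   WA%, n paths, exclusions), `measurements` (per-site tibble),
#'   `manifest`.
#' @export
run_subject <- function(config, subject_id, phantom = NULL, volumes = NULL) {
  man <- new_manifest(config, config$seed)
  if (is.null(phantom) && is.null(volumes)) {
    stop("either a phantom or a volumes list must be supplied", call. = FALSE)
  }
  if (!is.null(phantom)) {
    ct <- phantom$ct; ute <- phantom$ute; t2w <- phantom$t2w
    tr <- phantom$truth$tree
    root <- c(tr$x0[1], tr$y0[1], tr$z0[1]) +
      3 * c(tr$dx[1], tr$dy[1], tr$dz[1])
    lobe_map <- phantom$truth$lobe_map
    log_stage(man, "input", "ok", "phantom subject")
  } else {
    for (m in c("ct", "ute", "t2w")) {
      if (is.null(volumes[[m]])) {
        stop(sprintf("missing modality '%s' in volumes", m), call. = FALSE)
      }
    }
    ct <- volumes$ct; ute <- volumes$ute; t2w <- volumes$t2w
    root <- volumes$seed_mm
    lobe_map <- volumes$lobe_map
    log_stage(man, "input", "ok", "provided volumes")
  }
  man$checksums$ct <- digest::digest(ct$data)
  man$checksums$ute <- digest::digest(ute$data)
  man$checksums$t2w <- digest::digest(t2w$data)

  # 1. normalize the native T2w volume
  norm <- normalize_t2(t2w)
  log_stage(man, "normalize", "ok",
            sprintf("mu=%.3f sigma=%.3f", norm$mu_x, norm$sigma_x))

  # 2. register CT-like and normalized T2w-like onto the UTE-like reference
  # and measure; if the throughput registration settings leave the warped
  # CT unmeasurable (a QC failure), escalate once to the full-quality
  # registration schedule for this subject
  attempt <- function(rcfg) {
    reg_ct <- register_volumes(ct, ute, rcfg)
    log_stage(man, "register_ct", "ok",
              sprintf("edge similarity %.3f", reg_ct$similarity))
    reg_t2 <- register_volumes(norm$volume, ute, rcfg)
    log_stage(man, "register_t2", "ok",
              sprintf("edge similarity %.3f", reg_t2$similarity))
    res <- measure_airways(reg_ct$warped, reg_t2$warped, ute, root,
                           lobe_map, config, subject_id = subject_id,
                           man = man)
    res$t2_reg <- reg_t2$warped
    res
  }
  res <- tryCatch(attempt(do.call(register_config, config$register)),
                  error = function(e) NULL)
  if (is.null(res) || res$biomarkers$n_paths == 0) {
    log_stage(man, "register_retry", "escalated",
              "quality registration schedule")
    res <- attempt(register_config())
  }
  t2_reg <- res$t2_reg
  biomarkers <- dplyr::mutate(res$biomarkers,
                              alignment_score = res$qc_score,
                              mu_x = norm$mu_x, sigma_x = norm$sigma_x)
  sites_tbl <- res$sites
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(t2_reg, file.path(config$output_dir,
                                   paste0(subject_id, "_t2w_reg.nii.gz")))
    utils::write.csv(
      sites_tbl[, c("site_id", "lobe", "site", "LA", "WA", "WA_percent",
                    "status")],
      file.path(config$output_dir, paste0(subject_id, "_sections.csv")),
      row.names = FALSE)
  }
  list(biomarkers = biomarkers,
       measurements = sites_tbl[, c("site_id", "lobe", "branch_id", "site",
                                    "LA", "WA", "WA_percent", "status")],
       manifest = manifest_tibble(man))
}

#' Measure the airway biomarkers on co-registered volumes
#'
#' The measurement core of the pipeline, after normalization and
#' registration have put everything in the reference frame: lumen
#' segmentation, centerline tree with generation labels, lobar path
#' selection with mucus exclusion, two cross-sectional wall measurements
#' per path, wall-mask rasterization (lumen voxels excluded) and the
#' per-patient biomarkers.
#'
#' @param ct_reg CT-like [brw_volume()] in the reference frame.
#' @param t2_reg normalized T2w-like [brw_volume()] in the reference frame.
#' @param ref the reference-grid [brw_volume()] (UTE-like).
#' @param root_mm tracheal seed, world mm.
#' @param lobe_map lobe table (see [select_paths()]).
#' @param config config list (see [default_config()]).
#' @param subject_id identifier used in exclusion records.
#' @param man internal manifest environment (created if `NULL`).
#' @return A list: `biomarkers` (one-row tibble), `sites` (per-site tibble
#'   with measurements), `tree`, `mask`, `qc_score`.
#' @export
measure_airways <- function(ct_reg, t2_reg, ref, root_mm, lobe_map, config,
                            subject_id = "subject", man = NULL) {
  if (is.null(man)) man <- new_manifest(config, config$seed)
  root <- root_mm
  lumen <- segment_lumen(ct_reg, root,
                         threshold = config$airway$lumen_threshold)
  log_stage(man, "segment", "ok", sprintf("%d lumen voxels", sum(lumen)))
  qc <- check_alignment(lumen, ct_reg, ref,
                        threshold = config$qc$alignment_threshold)
  log_stage(man, "alignment_qc", if (qc$flagged) "flagged" else "ok",
            sprintf("score %.3f", qc$score))
  tree <- extract_centerline(lumen, spacing = ct_reg$spacing, root_mm = root,
                             prune_mm = config$airway$prune_mm)
  tree <- label_generations(tree)
  log_stage(man, "centerline", "ok",
            sprintf("%d branches", nrow(tree$branches)))
  sel <- select_paths(tree, lobe_map, ct = ct_reg)
  if (nrow(sel$excluded) > 0) {
    man$exclusions[[length(man$exclusions) + 1]] <-
      dplyr::mutate(sel$excluded, subject = subject_id, .before = 1)
  }
  log_stage(man, "select_paths", "ok",
            sprintf("%d paths, %d excluded", nrow(sel$paths),
                    nrow(sel$excluded)))

  site_rows <- list()
  site_id <- 0L
  for (p in seq_len(nrow(sel$paths))) {
    lobe <- sel$paths$lobe[p]
    sites <- tryCatch(
      pick_measurement_sites(tree, sel$paths$branch_id[p],
                             n_sites = config$measure$n_sites),
      error = function(e) NULL)
    if (is.null(sites)) {
      man$exclusions[[length(man$exclusions) + 1]] <- tibble::tibble(
        subject = subject_id, lobe = lobe,
        branch_id = sel$paths$branch_id[p],
        reason = "branch too short for measurement")
      next
    }
    for (s in seq_len(nrow(sites))) {
      site_id <- site_id + 1L
      sec <- reformat_cross_section(
        ct_reg, c(sites$cx[s], sites$cy[s], sites$cz[s]),
        c(sites$nx[s], sites$ny[s], sites$nz[s]),
        half_size_mm = config$measure$half_size_mm)
      meas <- detect_wall(sec, sigma_mm = config$measure$sigma_sweep,
                          n_rays = config$measure$n_rays)
      site_rows[[site_id]] <- tibble::tibble(
        site_id = site_id, lobe = lobe,
        branch_id = sites$branch_id[s], site = sites$site[s],
        cx = sites$cx[s], cy = sites$cy[s], cz = sites$cz[s],
        nx = sites$nx[s], ny = sites$ny[s], nz = sites$nz[s],
        e1 = list(sec$e1), e2 = list(sec$e2),
        LA = meas$LA, WA = meas$WA, WA_percent = meas$WA_percent,
        status = meas$status,
        measurement = list(meas)
      )
    }
  }
  sites_tbl <- dplyr::bind_rows(site_rows)
  if (nrow(sites_tbl) == 0 || !any(sites_tbl$status == "ok")) {
    log_stage(man, "measure", "failed", "no successful wall measurement")
    stop("no successful wall measurement for subject ", subject_id,
         call. = FALSE)
  }
  log_stage(man, "measure", "ok",
            sprintf("%d/%d sections measured", sum(sites_tbl$status == "ok"),
                    nrow(sites_tbl)))

  mask <- wall_mask_3d(sites_tbl, ref,
                       slab_half_mm = config$measure$slab_half_mm,
                       lumen_mask = lumen)
  bio <- brwall_t2_mis(mask, t2_reg, sites_tbl[, c("site_id", "lobe")])
  log_stage(man, "biomarkers", "ok",
            sprintf("BrWall_T2-MIS %.2f over %d paths", bio$brwall_t2_mis,
                    nrow(bio$per_path)))
  ok_tbl <- sites_tbl[sites_tbl$status == "ok", ]
  biomarkers <- tibble::tibble(
    subject = subject_id,
    brwall_t2_mis = bio$brwall_t2_mis,
    wa_percent = mean(tapply(ok_tbl$WA_percent, ok_tbl$lobe, mean)),
    n_paths = nrow(bio$per_path),
    n_excluded = length(man$exclusions)
  )
  list(biomarkers = biomarkers, sites = sites_tbl, tree = tree,
       mask = mask, qc_score = qc$score, biomarker_detail = bio)
}

#' Run a full cohort and its statistical report
#'
#' In `"phantom"` mode a synthetic cohort table is drawn with
#' [generate_cohort()], each patient's true biomarker value becomes the
#' phantom wall T2 signal, every subject's volumes are generated and pushed
#' through [run_subject()] (in seed-shuffled order, recorded in the
#' manifest), and the statistical battery is applied to the measured
#' biomarkers joined with the generated covariates. In `"table-only"` mode
#' the imaging stages are skipped and the statistics are computed directly
#' on the cohort table, which must then contain a `brwall_t2_mis` column.
#'
#' @param config config list; `config$cohort_mode` selects the mode.
#' @param cohort optional pre-built cohort tibble (table-only mode).
#' @return A list: `cohort` (per-patient table), `report`
#'   ([cohort_stats_report()] output), `manifest`.
#' @export
run_cohort <- function(config = default_config(), cohort = NULL) {
  man <- new_manifest(config, config$seed)
  mode <- config$cohort_mode
  if (mode == "table-only" || !is.null(cohort)) {
    if (is.null(cohort)) {
      cohort <- generate_cohort(cohort_spec(n_per_group = config$n_per_group,
                                            seed = config$seed))
    }
    log_stage(man, "cohort", "ok", sprintf("table-only, n=%d", nrow(cohort)))
    report <- cohort_stats_report(cohort)
    return(list(cohort = cohort, report = report,
                manifest = manifest_tibble(man)))
  }
  if (mode != "phantom") {
    stop("cohort_mode must be 'phantom' or 'table-only' (volume cohorts ",
         "are run per subject with run_subject)", call. = FALSE)
  }
  tab <- generate_cohort(cohort_spec(n_per_group = config$n_per_group,
                                     seed = config$seed))
  # measurement order is seed-shuffled (blinded, random-order reading)
  set.seed(config$seed + 1L)
  order_idx <- sample(nrow(tab))
  man$order <- tab$patient_id[order_idx]
  ph <- config$phantom
  rows <- list()
  for (i in order_idx) {
    spec_i <- phantom_spec(
      grid_shape = ph$grid_shape, voxel_size_mm = ph$voxel_size_mm,
      tree_depth = ph$tree_depth,
      wall_t2_signal = tab$brwall_true[i],
      deformation = ph$deformation,
      seed = config$seed * 1000L + i
    )
    sub_cfg <- config
    res <- run_subject(sub_cfg, tab$patient_id[i],
                       phantom = generate_phantom(spec_i))
    rows[[i]] <- res$biomarkers
    if (nrow(res$manifest$exclusions) > 0) {
      man$exclusions[[length(man$exclusions) + 1]] <- res$manifest$exclusions
    }
  }
  meas <- dplyr::bind_rows(rows) |>
    dplyr::rename(brwall_measured = "brwall_t2_mis",
                  wa_percent_measured = "wa_percent")
  # the measured biomarker replaces the generated reading; reader replicates
  # live on the generated scale, so reproducibility is not mixed in
  cohort_out <- dplyr::left_join(tab, meas,
                                 by = c("patient_id" = "subject")) |>
    dplyr::mutate(brwall_generated = .data$brwall_t2_mis,
                  brwall_t2_mis = .data$brwall_measured) |>
    dplyr::select(-dplyr::any_of(c("brwall_reader1b", "brwall_reader2")))
  log_stage(man, "cohort", "ok",
            sprintf("phantom cohort, n=%d measured", nrow(meas)))
  report <- cohort_stats_report(cohort_out)
  list(cohort = cohort_out, report = report, manifest = manifest_tibble(man))
}

#' Statistical report for a cohort table
#'
#' Applies the full battery: Shapiro-gated group comparisons of the
#' biomarkers and lung-function variables (geometric summaries where the
#' gate fires), ROC of BrWall_T2-MIS for severe vs non-severe with the
#' Youden operating point and exact CIs, whole-cohort and per-group Pearson
#' correlations, stepwise logistic regression of the frequent-exacerbator
#' outcome, reproducibility (ICC, Bland-Altman) when replicate readings are
#' present, and the quartile cross-classification ANOVAs when WA% is
#' present.
#'
#' @param cohort tibble with at least `group` (or logical `severe`) and
#'   `brwall_t2_mis`.
#' @return A `brw_stats_report` list of sections; `NULL` sections mean the
#'   required columns were absent.
#' @export
cohort_stats_report <- function(cohort) {
  stopifnot("brwall_t2_mis" %in% names(cohort))
  if (!"severe" %in% names(cohort)) {
    if (!"group" %in% names(cohort)) {
      stop("cohort needs a 'severe' or 'group' column", call. = FALSE)
    }
    cohort$severe <- cohort$group == "severe"
  }
  if (length(unique(cohort$severe)) < 2) {
    warning("single-group cohort: group statistics skipped")
    return(structure(list(note = "single-group cohort; statistics skipped"),
                     class = "brw_stats_report"))
  }
  sev <- cohort[cohort$severe, ]
  ns <- cohort[!cohort$severe, ]

  gate_vars <- c(feno_ppb = TRUE, eos_cells_ul = TRUE)
  cmp_vars <- intersect(
    c("brwall_t2_mis", "wa_percent", "fev1_pct_pred", "fvc_pct_pred",
      "fev1_fvc", "fef2575_pct_pred", "pef_l_min", "feno_ppb",
      "eos_cells_ul"),
    names(cohort))
  group_comparisons <- purrr::map_dfr(cmp_vars, function(v) {
    gc <- compare_groups_continuous(sev[[v]], ns[[v]],
                                    gate = isTRUE(gate_vars[v]))
    tibble::tibble(
      variable = v, transformed = gc$transformed,
      mean_severe = if (gc$transformed) exp(gc$group_a[["mean"]])
                    else gc$group_a[["mean"]],
      sd_severe = if (gc$transformed) exp(gc$group_a[["sd"]])
                  else gc$group_a[["sd"]],
      mean_non_severe = if (gc$transformed) exp(gc$group_b[["mean"]])
                        else gc$group_b[["mean"]],
      sd_non_severe = if (gc$transformed) exp(gc$group_b[["sd"]])
                      else gc$group_b[["sd"]],
      t = gc$t, p_value = gc$p_value)
  })

  roc <- roc_youden(cohort$brwall_t2_mis, cohort$severe)

  corr_vars <- intersect(
    c("fev1_pct_pred", "fvc_pct_pred", "fev1_fvc", "fef2575_pct_pred",
      "pef_l_min", "eos_cells_ul", "feno_ppb"),
    names(cohort))
  correlations <- NULL
  if (length(corr_vars) > 0) {
    corr_one <- function(d, scope) {
      purrr::map_dfr(corr_vars, function(v) {
        x <- d[[v]]
        logged <- v %in% c("eos_cells_ul", "feno_ppb")
        if (logged) x <- log(x)
        pc <- tryCatch(pearson_corr(d$brwall_t2_mis, x),
                       error = function(e) list(r = NA_real_,
                                                p_value = NA_real_,
                                                n = NA_integer_))
        tibble::tibble(scope = scope, variable = v, log_scale = logged,
                       r = pc$r, p_value = pc$p_value, n = pc$n)
      })
    }
    correlations <- dplyr::bind_rows(
      corr_one(cohort, "whole"), corr_one(sev, "severe"),
      corr_one(ns, "non-severe"))
  }

  regression <- NULL
  reg_pred <- intersect(c("fev1_pct_pred", "fvc_pct_pred", "fev1_fvc",
                          "feno_ppb", "eos_cells_ul", "brwall_t2_mis"),
                        names(cohort))
  if ("aer_ge2" %in% names(cohort) && length(unique(cohort$aer_ge2)) == 2) {
    regression <- stepwise_logistic(cohort, "aer_ge2", reg_pred)
  }

  reproducibility <- NULL
  if (all(c("brwall_reader1b", "brwall_reader2") %in% names(cohort))) {
    reproducibility <- list(
      intra_icc = icc_absolute(cbind(cohort$brwall_t2_mis,
                                     cohort$brwall_reader1b)),
      inter_icc = icc_absolute(cbind(cohort$brwall_t2_mis,
                                     cohort$brwall_reader2)),
      intra_ba = bland_altman(cohort$brwall_t2_mis, cohort$brwall_reader1b),
      inter_ba = bland_altman(cohort$brwall_t2_mis, cohort$brwall_reader2)
    )
  }

  quartiles <- NULL
  if ("wa_percent" %in% names(cohort) && nrow(cohort) >= 8) {
    quartiles <- list(
      brwall_by_wa = tryCatch(
        quartile_anova(cohort$wa_percent, cohort$brwall_t2_mis),
        error = function(e) NULL),
      wa_by_brwall = tryCatch(
        quartile_anova(cohort$brwall_t2_mis, cohort$wa_percent),
        error = function(e) NULL)
    )
  }

  structure(list(
    n = nrow(cohort), n_severe = nrow(sev), n_non_severe = nrow(ns),
    group_comparisons = group_comparisons, roc = roc,
    correlations = correlations, regression = regression,
    reproducibility = reproducibility, quartiles = quartiles
  ), class = "brw_stats_report")
}

#' @export
print.brw_stats_report <- function(x, ...) {
  if (!is.null(x$note)) { cat("<brw_stats_report>", x$note, "\n"); return(invisible(x)) }
  cat(sprintf("<brw_stats_report> %d patients (%d severe / %d non-severe)\n",
              x$n, x$n_severe, x$n_non_severe))
  gc <- x$group_comparisons
  b <- gc[gc$variable == "brwall_t2_mis", ]
  if (nrow(b) == 1) {
    cat(sprintf("  BrWall_T2-MIS: %.0f +/- %.0f vs %.0f +/- %.0f, p = %.3g\n",
                b$mean_severe, b$sd_severe, b$mean_non_severe,
                b$sd_non_severe, b$p_value))
  }
  print(x$roc)
  invisible(x)
}

#' Serialize a stats report to JSON
#'
#' @param report a `brw_stats_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "brw_roc")) {
      x <- x[c("auc", "auc_ci", "cutoff", "sensitivity", "sensitivity_ci",
               "specificity", "specificity_ci", "youden_j")]
    } else if (inherits(x, "brw_icc")) {
      x <- x[c("icc", "ci", "label")]
    } else if (inherits(x, "brw_bland_altman")) {
      x <- x[c("mean_diff", "ci", "sd_diff", "loa")]
    } else if (inherits(x, "brw_stepwise")) {
      x <- list(selected = x$selected, coefficients = x$coefficients,
                separation = x$separation)
    } else if (inherits(x, "brw_quartile_anova")) {
      x <- x[c("f", "p_value", "groups", "tukey")]
    }
    if (is.list(x) && !is.data.frame(x)) lapply(x, to_plain) else x
  }
  jsonlite::write_json(to_plain(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
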