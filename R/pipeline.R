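#' Study configuration for the end-to-end pipeline
#'
#' Bundles the cohort design, per-group generator presets, analysis flags and
#' the master seed. A run is reproducible from the configuration alone: every
#' stage derives its seed from `seed` by a fixed counter scheme
#' (stage `k` uses `derive_seed(seed, k)`, see [derive_seed()]).
#'
#' @param seed master seed.
#' @param design a [cohort_design()].
#' @param activity_presets named list of [activity_preset()] per group tag.
#' @param histology_presets named list of [histology_preset()]; must contain
#'   `ctr` plus one entry per lesioned group tag.
#' @param correlation a [metric_correlation_spec()].
#' @param n_correlation tendons drawn for the correlation analysis.
#' @param assessor_confusion probability of a one-step assessor error.
#' @param score_jitter probability that a tendon's true sub-score deviates
#'   one step from its group profile (biological variability).
#' @param baseline_days pre-surgery days in the activity baseline.
#' @param exclude_days day indices excluded from light-period analyses
#'   (surgery and food-supplementation days by default).
#' @param kappa_weights weighted-kappa scheme, `"linear"` or `"quadratic"`.
#' @param welch use Welch's t-test instead of pooled.
#' @param direction_mode `"ratio"` or `"deviation"` for direction
#'   normalization.
#' @param aggregation_days day window of the control-normalized aggregate.
#' @param tendons_imaged_per_group tendons per group that get synthetic
#'   microscopy fields (image stages are the slow part; the remaining tendons
#'   enter via the metric cohort).
#' @param fields_per_area fields per tendon area (1-4).
#' @param write_traces,write_images also write raw minute traces / TIFF
#'   fields (off by default; summaries are always written).
#' @return a `study_config` object.
#' @export
study_config <- function(seed = 1,
                         design = study_cohort_design(),
                         activity_presets = study_activity_presets(),
                         histology_presets = study_histology_presets(),
                         correlation = study_correlation_spec(),
                         n_correlation = 52,
                         assessor_confusion = 0.1,
                         score_jitter = 0.2,
                         baseline_days = 3,
                         exclude_days = c(0, 14),
                         kappa_weights = "linear",
                         welch = FALSE,
                         direction_mode = "ratio",
                         aggregation_days = 0:27,
                         tendons_imaged_per_group = 1,
                         fields_per_area = 4,
                         write_traces = FALSE,
                         write_images = FALSE) {
  structure(as.list(environment()), class = "study_config")
}

#' Reduced-scale demonstration configuration
#'
#' Same structure as the packaged study but with two animals and two imaged
#' tendons per group, three pre-surgery days, small 120 x 90 um fields with
#' about 12 nuclei, and two fields per area, so a full run takes seconds.
#'
#' @param seed master seed.
#' @param ... overrides passed to [study_config()].
#' @return a `study_config`.
#' @export
demo_config <- function(seed = 1, ...) {
  design <- study_cohort_design()
  design$groups$n_animals <- pmin(design$groups$n_animals, 2)
  design$groups$n_tendons <- pmin(design$groups$n_tendons, 2)
  ap <- lapply(study_activity_presets(), function(p) {
    p$n_days_pre <- 3L
    p
  })
  hp <- lapply(study_histology_presets(), function(p) {
    histology_preset(
      nuclei_per_field_mean = p$nuclei_per_field_mean / 6,
      orientation_mean = p$orientation_mean,
      orientation_sd = p$orientation_sd,
      min_center_distance = p$min_center_distance,
      field_size = c(120, 90))
  })
  study_config(seed = seed, design = design, activity_presets = ap,
               histology_presets = hp, n_correlation = 52,
               fields_per_area = 2, ...)
}

#' Per-group true ordinal score profiles used by the generator
#'
#' Healthy controls sit at the rubric maximum; lesioned groups are ordered
#' bilateral-free best to unilateral-blocked worst.
#'
#' @return data.frame with one row per group tag and the six sub-scores.
#' @export
true_score_profiles <- function() {
  data.frame(
    group = c("ctr_free", "ctr_blocked", "bilateral_free", "bilateral_blocked",
              "unilateral_free", "unilateral_blocked"),
    cellularity = c(3, 3, 2, 2, 2, 1),
    alignment   = c(3, 3, 2, 2, 1, 1),
    col1        = c(3, 3, 2, 1, 1, 1),
    vascularity = c(3, 3, 2, 2, 1, 2),
    chondro     = c(3, 3, 1, 1, 2, 2),
    osteo       = c(3, 3, 3, 3, 3, 3))
}

# internal: representative semi-quantitative observation for a true score
observation_from_score <- function(parameter, score) {
  switch(parameter,
    col1 = c(`0` = 0, `1` = 2, `2` = 3, `3` = 5)[as.character(score)],
    vascularity = scoring_rules()$vascularity$levels[score + 1],
    metaplasia = c(`0` = 5, `1` = 3, `2` = 1, `3` = 0)[as.character(score)],
    stop("unknown parameter"))
}

#' Validate a study configuration
#'
#' Checks every structural invariant and returns the violations (empty when
#' the configuration is runnable); [run_study()] refuses to start otherwise.
#'
#' @param config a `study_config`.
#' @return character vector of violations, each prefixed with a path into the
#'   configuration.
#' @export
validate_config <- function(config) {
  v <- character(0)
  push <- function(msg) v <<- c(v, msg)
  if (!inherits(config, "study_config")) {
    return("config: not a study_config object")
  }
  d <- config$design
  if (!inherits(d, "cohort_design") || nrow(d$groups) == 0) {
    push("design: missing or empty cohort design")
  } else {
    for (g in d$groups$group) {
      if (is.null(config$activity_presets[[g]])) {
        push(sprintf("activity_presets$%s: missing preset for group", g))
      }
      hkey <- if (startsWith(g, "ctr")) "ctr" else g
      if (is.null(config$histology_presets[[hkey]])) {
        push(sprintf("histology_presets$%s: missing preset for group", hkey))
      }
    }
  }
  cs <- config$correlation
  if (!inherits(cs, "metric_correlation_spec")) {
    push("correlation: not a metric_correlation_spec")
  } else {
    ev <- eigen((cs$rho + t(cs$rho)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      push(sprintf("correlation$rho: not positive semi-definite (smallest eigenvalue %.4g)",
                   min(ev)))
    }
    if (max(abs(diag(cs$rho) - 1)) > 1e-8) push("correlation$rho: diagonal not 1")
  }
  if (config$assessor_confusion < 0 || config$assessor_confusion > 0.5) {
    push("assessor_confusion: must be in [0, 0.5]")
  }
  if (config$score_jitter < 0 || config$score_jitter > 0.5) {
    push("score_jitter: must be in [0, 0.5]")
  }
  if (config$baseline_days < 1) push("baseline_days: must be >= 1")
  if (inherits(d, "cohort_design")) {
    pre <- vapply(d$groups$group, function(g) {
      p <- config$activity_presets[[g]]
      if (is.null(p)) NA_integer_ else p$n_days_pre
    }, integer(1))
    if (any(!is.na(pre) & pre < config$baseline_days)) {
      push("baseline_days: exceeds n_days_pre of at least one activity preset")
    }
  }
  if (!config$fields_per_area %in% 1:4) push("fields_per_area: must be 1-4")
  if (config$tendons_imaged_per_group < 1) {
    push("tendons_imaged_per_group: must be >= 1")
  }
  if (config$n_correlation < 4) push("n_correlation: must be >= 4")
  if (!config$kappa_weights %in% c("linear", "quadratic")) {
    push("kappa_weights: must be linear or quadratic")
  }
  if (!config$direction_mode %in% c("ratio", "deviation")) {
    push("direction_mode: must be ratio or deviation")
  }
  v
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes every stage in order — activity simulation and metrics, synthetic
#' histology and tendon metrics, metric-cohort correlation analysis, scoring
#' and THS, assessor agreement, and group statistics — writing every
#' intermediate table under `out_dir` so each stage is independently
#' re-runnable. Identical configurations produce byte-identical tables.
#'
#' @param config a `study_config`; [validate_config()] must pass.
#' @param out_dir output directory.
#' @param force overwrite a non-empty `out_dir`.
#' @return a `report_bundle`: list with `out_dir`, named `files`, `config`,
#'   `version` and the stage `log`, invisibly.
#' @export
run_study <- function(config, out_dir, force = FALSE) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  files <- list()
  keep <- function(name, path) files[[name]] <<- path
  csv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    keep(sub("\\.csv$", "", name), path)
  }
  groups <- config$design$groups
  logf("stage activity: simulating %d cages", sum(groups$n_animals))
  logf("flags: baseline_days=%d exclude_days=%s kappa_weights=%s welch=%s direction_mode=%s",
       config$baseline_days, paste(config$exclude_days, collapse = ","),
       config$kappa_weights, config$welch, config$direction_mode)

  ## ---- stage 1: activity simulation + metrics --------------------------
  s_act <- derive_seed(config$seed, 1)
  traces <- list(); cage_meta <- list(); k <- 0
  for (gi in seq_len(nrow(groups))) {
    g <- groups$group[gi]
    for (ai in seq_len(groups$n_animals[gi])) {
      k <- k + 1
      id <- sprintf("%s_%02d", g, ai)
      tr <- simulate_activity(config$activity_presets[[g]], group = g,
                              seed = s_act + k, cage_id = id)
      traces[[id]] <- tr
      cage_meta[[id]] <- g
      if (config$write_traces) {
        write_activity_csv(tr, file.path(out_dir, paste0("trace_", id, ".csv")))
      }
    }
  }
  daily <- do.call(rbind, lapply(names(traces), function(id) {
    d <- split_day_night(traces[[id]])
    cbind(cage_id = id, group = cage_meta[[id]], d)
  }))
  # light-period analyses exclude the configured days (surgery, food top-up)
  daily$light_mean[daily$day_index %in% config$exclude_days] <- NA
  csv(daily, "daily_activity.csv")
  binned <- do.call(rbind, lapply(names(traces), function(id) {
    b <- bin_3h(traces[[id]])
    cbind(cage_id = id, group = cage_meta[[id]], b)
  }))
  csv(binned, "binned_activity.csv")
  n_pre <- min(vapply(config$activity_presets[groups$group],
                      function(p) p$n_days_pre, integer(1)))
  periods <- study_periods(n_pre)
  period_means <- do.call(rbind, lapply(unique(groups$group), function(g) {
    cbind(group = g,
          aggregate_bins_by_period(binned[binned$group == g, ], periods))
  }))
  csv(period_means, "bin_period_means.csv")
  normalized <- lapply(names(traces), function(id) {
    d <- split_day_night(traces[[id]])
    normalize_to_baseline(d, config$baseline_days, cage_id = id)
  })
  names(normalized) <- names(traces)
  norm_df <- do.call(rbind, lapply(names(traces), function(id) {
    cbind(cage_id = id, group = cage_meta[[id]], normalized[[id]])
  }))
  csv(norm_df, "normalized_activity.csv")

  grp_of <- unlist(cage_meta)
  ctrl_ratios <- NULL
  for (g in unique(groups$group[groups$lesion != "none"])) {
    wheel <- sub(".*_", "", g)
    ctrl_tag <- paste0("ctr_", wheel)
    if (!ctrl_tag %in% grp_of) next
    ratios <- normalize_to_control(normalized[grp_of == g],
                                   normalized[grp_of == ctrl_tag],
                                   days = config$aggregation_days)
    ctrl_ratios <- rbind(ctrl_ratios,
                         data.frame(cage_id = names(normalized[grp_of == g]),
                                    group = g, control = ctrl_tag,
                                    ratio = ratios))
  }
  if (!is.null(ctrl_ratios)) csv(ctrl_ratios, "control_normalized.csv")

  ## ---- stage 2: synthetic histology + tendon metrics -------------------
  logf("stage histology: %d tendons per group, %d fields per area",
       config$tendons_imaged_per_group, config$fields_per_area)
  s_his <- derive_seed(config$seed, 2)
  fcount <- 0
  gen_tendon <- function(preset, tendon_id) {
    fields <- list()
    for (a in 1:5) {
      for (f in seq_len(config$fields_per_area)) {
        fcount <<- fcount + 1
        fields[[length(fields) + 1]] <-
          simulate_histology_field(preset, area_index = a, field_index = f,
                                   seed = s_his + fcount,
                                   tendon_id = tendon_id)
      }
    }
    fields
  }
  ctr_groups <- groups$group[groups$lesion == "none"]
  healthy_fields <- list()
  tendon_rows <- list()
  all_metrics <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups$group[gi]
    hkey <- if (startsWith(g, "ctr")) "ctr" else g
    for (ti in seq_len(min(config$tendons_imaged_per_group, groups$n_tendons[gi]))) {
      id <- sprintf("%s_t%02d", g, ti)
      flds <- gen_tendon(config$histology_presets[[hkey]], id)
      if (g %in% ctr_groups) healthy_fields <- c(healthy_fields, flds)
      all_metrics[[id]] <- list(group = g, fields = flds)
      if (config$write_images) {
        for (fl in flds) {
          write_field_tiff(fl, file.path(out_dir, sprintf(
            "field_%s_a%d_f%d.tiff", id, fl$area_index, fl$field_index)))
        }
      }
    }
  }
  healthy <- if (length(healthy_fields)) {
    ctr_metrics <- assemble_tendon_metrics(healthy_fields)
    healthy_reference(mean_count = ctr_metrics$mean_count,
                      direction = ctr_metrics$direction,
                      dispersion = ctr_metrics$dispersion)
  } else {
    healthy_reference()
  }
  for (id in names(all_metrics)) {
    m <- assemble_tendon_metrics(all_metrics[[id]]$fields, healthy = healthy,
                                 direction_mode = config$direction_mode)
    tendon_rows[[id]] <- data.frame(
      tendon_id = id, group = all_metrics[[id]]$group,
      mean_count = m$mean_count, fold_change = m$fold_change,
      direction = m$direction, dispersion = m$dispersion,
      direction_ratio = m$direction_ratio,
      total_area_mm2 = m$total_area_mm2)
  }
  csv(do.call(rbind, tendon_rows), "tendon_metrics.csv")

  ## ---- stage 3: metric cohort + correlation ----------------------------
  lesioned <- groups$lesion != "none"
  cohort <- NULL
  if (any(lesioned)) {
    s_coh <- derive_seed(config$seed, 3)
    cohort <- simulate_metric_cohort(config$correlation, config$n_correlation,
                                     seed = s_coh)
    csv(cohort, "metric_cohort.csv")
    corr <- pearson_matrix(cohort)
    csv(corr, "correlation_matrix.csv")
    jsonlite::write_json(corr, file.path(out_dir, "correlation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    keep("correlation_json", file.path(out_dir, "correlation.json"))
    logf("stage correlation: %d tendons, %d pairs", nrow(cohort), nrow(corr))
  } else {
    logf("stage correlation: skipped (control-only design, no lesion variance)")
  }

  ## ---- stage 4: scoring, THS, agreement --------------------------------
  s_sco <- derive_seed(config$seed, 4)
  profiles <- true_score_profiles()
  tendon_groups <- rep(groups$group, groups$n_tendons)
  params <- c("cellularity", "alignment", "col1", "vascularity",
              "chondro", "osteo")
  true_scores <- sapply(params, function(p) {
    base <- profiles[[p]][match(tendon_groups, profiles$group)]
    jit <- simulate_assessors(base, config$score_jitter,
                              seed = s_sco + match(p, params), parameter = p)
    jit$assessor_a  # one jittered realization per tendon
  })
  cards <- lapply(seq_along(tendon_groups), function(i) {
    do.call(total_histological_score, as.list(true_scores[i, ]))
  })
  card_df <- data.frame(tendon_id = sprintf("%s_t%02d", tendon_groups,
                                            unlist(lapply(groups$n_tendons, seq_len))),
                        group = tendon_groups)
  for (p in params) card_df[[p]] <- true_scores[, p]
  card_df$ths <- vapply(cards, function(c) c$ths, numeric(1))
  csv(card_df, "score_cards.csv")
  csv(ths_summary(cards, tendon_groups), "ths_summary.csv")

  s_agr <- derive_seed(config$seed, 5)
  agr <- list()
  for (p in c("col1", "vascularity", "chondro", "osteo")) {
    tab <- simulate_assessors(true_scores[, p], config$assessor_confusion,
                              seed = s_agr + match(p, params), parameter = p)
    res <- agreement_summary(tab, weights = config$kappa_weights)
    agr[[p]] <- list(percent_agreement = res$percent_agreement,
                     kappa = res$kappa, weighted_kappa = res$weighted_kappa,
                     weights = res$weights, n = res$n)
    csv(as.data.frame.matrix(res$confusion), paste0("confusion_", p, ".csv"))
  }
  jsonlite::write_json(agr, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  keep("agreement_json", file.path(out_dir, "agreement.json"))

  ## ---- stage 5: group statistics ---------------------------------------
  stats_out <- list()
  if (length(unique(tendon_groups)) >= 2) {
    av <- one_way_anova_tukey(card_df$ths, card_df$group)
    stats_out$ths_anova <- list(F = av$F, df = av$df, p = av$p,
                                tukey = av$tukey)
  }
  if (!is.null(ctrl_ratios)) {
    bf <- ctrl_ratios$ratio[ctrl_ratios$group == "bilateral_free"]
    bb <- ctrl_ratios$ratio[ctrl_ratios$group == "bilateral_blocked"]
    if (length(bf) >= 2 && length(bb) >= 2) {
      stats_out$bilateral_wheel_t <-
        independent_t_test(bf, bb, welch = config$welch)
    }
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  keep("group_stats_json", file.path(out_dir, "group_stats.json"))

  ## ---- bundle ----------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), cfg_path)
  keep("config", cfg_path)
  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  keep("log", log_path)
  bundle <- list(out_dir = out_dir, files = files,
                 config = config,
                 version = as.character(packageVersion("tendonwatch")),
                 log = log_lines)
  jsonlite::write_json(
    list(version = bundle$version,
         files = lapply(files, basename)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE)
  class(bundle) <- "report_bundle"
  invisible(bundle)
}
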