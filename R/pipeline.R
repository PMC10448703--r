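# End-to-end orchestration: preprocess -> tensorize -> decompose -> screen
# -> infer for both branches and hemispheres, plus the grand-averaging
# comparison.  Fully deterministic given (config, seed).

# run component-wise ANOVA, sum significant components, locate TOI/ROI and
# run the follow-up; shared by both branches
infer_effects <- function(tests, comps, hrfs, design, epoch, times, channels,
                          config) {
  profiles <- select_and_sum(tests, comps, alpha = config$alpha,
                             fdr = config$fdr)
  effects <- list()
  for (eff in names(profiles)) {
    ps <- profiles[[eff]]
    toi <- determine_toi(ps, times, epoch, config$toi_half_width_s,
                         config$toi_post_peak_frac)
    roi <- determine_roi(ps, channels, config$roi_fraction)
    followup <- NULL
    if (!is.null(toi) && length(roi) > 0) {
      contrasts <- if (eff == "main_b")
        lapply(design$levels_a, function(la) list(factor = "b", level_a = la))
      else
        lapply(design$levels_b, function(lb) list(factor = "a", level_b = lb))
      followup <- tryCatch(
        bayes_followup(hrfs, toi, roi, design, contrasts, config$bf_rscale),
        error = function(e) NULL)
    }
    effects[[eff]] <- list(profile = ps, toi = toi, roi = roi,
                           followup = followup)
  }
  effects
}

tests_to_table <- function(tests, ids, alpha) {
  if (length(tests) == 0)
    return(data.frame(id = character(), effect = character(), F = numeric(),
                      p = numeric(), significant = logical()))
  out <- do.call(rbind, lapply(seq_along(tests), function(i)
    cbind(id = ids[i], tests[[i]])))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

run_branch_td <- function(hrfs_h, design, epoch, config) {
  tens <- build_tensor_td(hrfs_h, design)
  sel <- select_ranks_td(tens, config$rt_max, config$rc_max,
                         config$error_threshold)
  model <- orthogonal_tucker(tens, sel$ranks, tol = config$td_tol,
                             max_iter = config$td_max_iter)
  model$meta <- tens[c("mode_axes", "hemisphere", "subjects", "design")]
  screened <- screen_components(model, times = epoch$times, epoch = epoch,
                                temporal_threshold = config$temporal_threshold)
  kept_rt <- screened$comp[screened$retained]
  combos <- expand.grid(rt = kept_rt, rc = seq_len(model$ranks[["Rc"]]))
  tests <- list(); comps <- list()
  for (i in seq_len(nrow(combos))) {
    rt <- combos$rt[i]; rc <- combos$rc[i]
    sc <- subject_scores_td(model, rt, rc)
    tests[[i]] <- anova_2x2(sc, design, tens$subjects)
    comps[[i]] <- list(temporal = model$factors$time[, rt],
                       spatial = model$factors$channel[, rc], weight = 1,
                       id = sprintf("td-rt%d-rc%d", rt, rc))
  }
  effects <- infer_effects(tests, comps, hrfs_h, design, epoch,
                           times = epoch$times,
                           channels = tens$mode_axes$channel, config)
  list(branch = "td", hemisphere = tens$hemisphere,
       ranks = model$ranks, rank_selection = sel, model = model,
       screened = screened, n_tested = length(tests),
       anova = tests_to_table(tests, vapply(comps, `[[`, "", "id"),
                              config$alpha),
       effects = effects)
}

run_branch_cpd <- function(hrfs_h, design, epoch, config, seed) {
  tens <- build_tensor_cpd(hrfs_h, design, config$stft_window_s,
                           config$stft_overlap)
  sel <- select_rank_cpd(tens, config$r_max, config$error_threshold,
                         seed = seed, max_iter = config$cpd_max_iter,
                         tol = config$cpd_tol)
  runs <- run_cpd_ensemble(tens, sel$rank, config$n_runs, seed = seed,
                           max_iter = config$cpd_max_iter,
                           tol = config$cpd_tol)
  screened <- screen_components(runs, times = tens$mode_axes$time,
                                epoch = epoch, freqs = tens$mode_axes$freq,
                                temporal_threshold = config$temporal_threshold,
                                spectral_cutoff_hz = config$spectral_cutoff_hz,
                                spectral_method = config$spectral_method)
  consensus <- match_components_across_runs(runs, screened,
                                            r_threshold = config$consensus_r,
                                            alpha = config$alpha,
                                            mode = config$consensus_mode)
  tests <- list(); comps <- list()
  for (cc in consensus) {
    for (j in seq_len(nrow(cc$members))) {
      run <- cc$members$run[j]; r <- cc$members$comp[j]
      sc <- subject_scores_cpd(runs[[run]], r)
      cv <- comp_vectors(runs[[run]], r)
      i <- length(tests) + 1L
      tests[[i]] <- anova_2x2(sc, design, tens$subjects)
      comps[[i]] <- list(temporal = cv$time, spatial = cv$channel,
                         spectral = cv$freq, weight = cc$occurrence_weight,
                         id = sprintf("cpd-run%d-c%d", run, r))
    }
  }
  effects <- infer_effects(tests, comps, hrfs_h, design, epoch,
                           times = tens$mode_axes$time,
                           channels = tens$mode_axes$channel, config)
  list(branch = "cpd", hemisphere = tens$hemisphere, rank = sel$rank,
       rank_selection = sel, runs = runs, screened = screened,
       consensus = consensus, n_tested = length(tests),
       anova = tests_to_table(tests, vapply(comps, `[[`, "", "id"),
                              config$alpha),
       effects = effects)
}

#' Run the full TOI/ROI discovery pipeline
#'
#' Builds trial-averaged HRFs, splits them by hemisphere and runs the
#' nonnegative-CPD and/or orthogonal-Tucker branches per hemisphere:
#' tensorisation, rank selection, decomposition (with cross-run consensus
#' for CPD), component screening, component-wise 2x2 ANOVA, profile
#' summation, TOI/ROI determination and Bayes-factor follow-up.  When a
#' predefined TOI window and ROI are supplied, the grand-averaging baseline
#' is run alongside for comparison.
#'
#' @param recordings list of [fnirs_recording()] (ignored when `sim_spec`
#'   is given)
#' @param design a [design_info()] (taken from the simulation when
#'   `sim_spec` is given)
#' @param epoch an [epoch_definition()] (idem)
#' @param sim_spec optional [simulation_spec()]; the dataset is generated
#'   and analysed, and the ground truth is attached to the report
#' @param config configuration list from [load_config()]/[default_config()]
#' @param seed master seed for the stochastic CPD stages
#' @param method `"both"`, `"cpd"` or `"td"`
#' @param predefined_toi,predefined_roi optional grand-averaging inputs
#' @param out_dir optional directory for the JSON/TSV report bundle
#' @return a list of class `nirs_pipeline_report`
#' @export
run_pipeline <- function(recordings = NULL, design = NULL, epoch = NULL,
                         sim_spec = NULL, config = default_config(),
                         seed = 1, method = c("both", "cpd", "td"),
                         predefined_toi = NULL, predefined_roi = NULL,
                         out_dir = NULL) {
  method <- match.arg(method)
  ground_truth <- NULL
  hemisphere_map <- NULL
  if (!is.null(sim_spec)) {
    nt_log("simulate", seed = sim_spec$seed,
           subjects = "from spec", effects = length(sim_spec$effects))
    sim <- simulate_dataset(sim_spec)
    recordings <- sim$recordings; design <- sim$design; epoch <- sim$epoch
    hemisphere_map <- sim$hemisphere_map
    ground_truth <- sim$ground_truth
  }
  if (is.null(recordings) || is.null(design) || is.null(epoch))
    nt_stop("need recordings + design + epoch, or a sim_spec")
  if (is.null(hemisphere_map)) hemisphere_map <- recordings[[1]]$hemisphere_map

  nt_log("preprocess", subjects = length(recordings))
  hrfs <- unlist(lapply(recordings, build_hrf, epoch = epoch, design = design,
                        baseline_correct = config$baseline_correct),
                 recursive = FALSE)
  split <- split_hemispheres(hrfs, hemisphere_map)

  hemis <- list()
  for (h in intersect(config$hemispheres, names(split))) {
    if (length(split[[h]]) == 0) next
    nt_log("analyse", hemisphere = h, method = method)
    branch <- list()
    if (method %in% c("both", "td"))
      branch$td <- run_branch_td(split[[h]], design, epoch, config)
    if (method %in% c("both", "cpd"))
      branch$cpd <- run_branch_cpd(split[[h]], design, epoch, config, seed)
    hemis[[h]] <- branch
  }

  grandavg <- NULL
  if (!is.null(predefined_toi) && !is.null(predefined_roi)) {
    nt_log("grandavg", toi = paste(predefined_toi, collapse = "-"),
           roi = paste(predefined_roi, collapse = ","))
    values <- grand_average(hrfs, predefined_toi, predefined_roi)
    grandavg <- list(toi = predefined_toi, roi = predefined_roi,
                     values = values, test = grandavg_test(values, design))
  }

  report <- structure(list(
    seed = seed, method = method, config = config, design = design,
    epoch = epoch, hemispheres = hemis, grand_averaging = grandavg,
    ground_truth = ground_truth
  ), class = "nirs_pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.nirs_pipeline_report <- function(x, ...) {
  cat(sprintf("TOI/ROI discovery report (seed %d, method %s)\n", x$seed,
              x$method))
  for (h in names(x$hemispheres)) {
    for (b in names(x$hemispheres[[h]])) {
      br <- x$hemispheres[[h]][[b]]
      cat(sprintf("  %s / %s: %d component tests\n", h, toupper(b),
                  br$n_tested))
      for (eff in names(br$effects)) {
        e <- br$effects[[eff]]
        toi_txt <- if (is.null(e$toi)) "no TOI"
                   else sprintf("TOI [%.1f, %.1f] s (peak %.1f s)",
                                e$toi$start_s, e$toi$end_s, e$toi$peak_time_s)
        cat(sprintf("    %s: %s; ROI {%s}\n", eff, toi_txt,
                    paste(e$roi, collapse = ", ")))
        for (f in e$followup %||% list())
          cat(sprintf("      %s: BF10 = %.3g\n", f$contrast, f$BF10))
      }
    }
  }
  if (!is.null(x$grand_averaging)) {
    cat("  grand averaging (predefined TOI/ROI):\n")
    t <- x$grand_averaging$test
    for (i in seq_len(nrow(t)))
      cat(sprintf("    %s: F = %.3f, p = %.4f\n", t$effect[i], t$F[i], t$p[i]))
  }
  invisible(x)
}

# JSON-serialisable view of a report (profiles, TOI/ROI, tests, BFs)
report_to_list <- function(report) {
  eff_list <- function(e) list(
    toi = if (is.null(e$toi)) NULL else
      list(start_s = e$toi$start_s, end_s = e$toi$end_s,
           peak_time_s = e$toi$peak_time_s),
    roi = as.list(e$roi),
    n_components = e$profile$n_components,
    weighted_count = e$profile$weighted_count,
    followup = lapply(e$followup %||% list(), function(f)
      list(contrast = f$contrast, BF10 = f$BF10, t = f$t,
           means = as.list(f$means), sds = as.list(f$sds)))
  )
  br_list <- function(br) list(
    branch = br$branch,
    rank = if (br$branch == "cpd") br$rank else as.list(br$ranks),
    n_tested = br$n_tested,
    effects = lapply(br$effects, eff_list)
  )
  list(
    seed = report$seed, method = report$method,
    hemispheres = lapply(report$hemispheres, function(hh)
      lapply(hh, br_list)),
    grand_averaging = if (is.null(report$grand_averaging)) NULL else list(
      toi = report$grand_averaging$toi, roi = report$grand_averaging$roi,
      test = report$grand_averaging$test)
  )
}

#' Write a pipeline report bundle
#'
#' Writes `report.json` (TOI/ROI, component counts, follow-up Bayes
#' factors), plus per-branch ANOVA and screening TSV tables.
#'
#' @param report a [run_pipeline()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (h in names(report$hemispheres)) {
    for (b in names(report$hemispheres[[h]])) {
      br <- report$hemispheres[[h]][[b]]
      utils::write.table(br$anova,
                         file.path(dir, sprintf("anova_%s_%s.tsv", h, b)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_screening_report(br$screened,
                             file.path(dir, sprintf("screening_%s_%s.tsv", h, b)))
    }
  }
  invisible(dir)
}
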