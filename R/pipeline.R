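# Orchestration: simulate/load -> preprocess -> detect -> features ->
# validity, as configured, reproducible runs with full per-bout accounting.

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML layout: `preprocess`
#' (confidence_threshold, cutoff_hz, filter_order, max_gap_frames),
#' `heelstrike` (eps_spatial, eps_hip_frac, eps_temporal, min_pts,
#' normalize_by_hip_width, min_stance_s), `features` (min_steps, max_steps,
#' unbiased_cv) and `stats` (bonferroni_factor, cutoffs).
#'
#' @param overrides Optional nested list merged over the defaults.
#' @return Configuration list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    preprocess = list(confidence_threshold = NULL, cutoff_hz = 8,
                      filter_order = 2, max_gap_frames = 15),
    heelstrike = list(eps_spatial = NULL, eps_hip_frac = 0.06,
                      eps_temporal = 0.13, min_pts = 4,
                      normalize_by_hip_width = FALSE, min_stance_s = 0.3,
                      noise_eps_mult = 2.0, min_stride_s = 0.65),
    features = list(min_steps = 3, max_steps = 20, unbiased_cv = TRUE),
    stats = list(bonferroni_factor = NULL, cutoffs = 5:40)
  )
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the blocks documented in
#'   [default_config()]; missing values fall back to the defaults.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

.as_pre_cfg <- function(cfg) {
  do.call(preprocess_config, cfg$preprocess)
}

.as_hs_params <- function(cfg) {
  do.call(stdbscan_params, cfg$heelstrike)
}

#' Extract gait features from one bout
#'
#' The canonical per-bout pipeline: confidence masking, gap interpolation,
#' zero-phase smoothing, per-foot ST-DBSCAN stance detection, heel-strike
#' extraction (automatic, and manual if annotations are given), foot
#' merging and feature computation.
#'
#' @param seq A raw [pose_sequence()].
#' @param bout A [bout_meta()].
#' @param annotations Optional [annotation_set()] for the manual method.
#' @param config Pipeline configuration (see [default_config()]).
#' @return List with `features` (0-2 rows: auto and/or manual),
#'   `events` (all heel strikes), `exclusions` (reasons for any method
#'   that produced no features) and `diagnostics` (per-stage counts).
#' @export
extract_bout <- function(seq, bout, annotations = NULL,
                         config = default_config()) {
  pre <- .as_pre_cfg(config)
  hs <- .as_hs_params(config)
  feats <- list()
  events <- list()
  excl <- list()
  diag <- list(bout_id = bout$bout_id)
  note_excl <- function(method, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(
      bout_id = bout$bout_id, annotation_method = method, reason = reason)
  }
  pp <- tryCatch(preprocess_sequence(seq, pre, estimator = bout$estimator),
                 error = function(e) e)
  if (inherits(pp, "error")) {
    note_excl("auto", conditionMessage(pp))
    note_excl("manual", conditionMessage(pp))
    return(list(features = NULL, events = NULL,
                exclusions = do.call(rbind, excl), diagnostics = diag))
  }
  diag$masked_fraction <- mean(attr(pp, "masked_fraction"))
  diag$usable_range <- attr(pp, "usable_range")
  hipw <- hip_width(pp)
  direction <- if (bout$direction != "unknown") bout$direction else
    infer_direction(pp)

  finish <- function(strikes, method) {
    f <- tryCatch(compute_features(strikes, pp, hipw,
                                   unbiased_cv = config$features$unbiased_cv),
                  error = function(e) e)
    if (inherits(f, "error")) {
      note_excl(method, conditionMessage(f))
      return(NULL)
    }
    f$annotation_method <- method
    f$bout_id <- bout$bout_id
    f$estimator <- bout$estimator
    f$direction <- direction
    f$subject_id <- bout$subject_id
    f$treatment_state <- bout$treatment_state
    f
  }

  auto <- tryCatch({
    st_l <- detect_stances(pp, "left", hs, bout)
    st_r <- detect_stances(pp, "right", hs, bout)
    diag$stances <- nrow(st_l) + nrow(st_r)
    merge_feet(heel_strikes_auto(st_l, pp), heel_strikes_auto(st_r, pp))
  }, error = function(e) e)
  if (inherits(auto, "error")) {
    note_excl("auto", conditionMessage(auto))
  } else {
    auto$bout_id <- bout$bout_id
    events[["auto"]] <- auto
    feats[["auto"]] <- finish(auto, "auto")
  }
  if (!is.null(annotations)) {
    man <- tryCatch({
      ev <- heel_strikes_manual(annotations, pp)
      merge_feet(ev[ev$foot == "left", ], ev[ev$foot == "right", ])
    }, error = function(e) e)
    if (inherits(man, "error")) {
      note_excl("manual", conditionMessage(man))
    } else {
      man$bout_id <- bout$bout_id
      events[["manual"]] <- man
      feats[["manual"]] <- finish(man, "manual")
    }
  }
  list(features = if (length(feats)) do.call(rbind, feats) else NULL,
       events = if (length(events)) do.call(rbind, events) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL,
       diagnostics = diag)
}

#' Run feature extraction over a cohort
#'
#' Applies [extract_bout()] to every bout of a simulated cohort (or a list
#' of `list(seq, bout, annotations)` items) and assembles the features
#' table, the events table and the exclusion report.  Every input bout
#' appears in the features table or in the exclusion report, per
#' annotation method.
#'
#' @param cohort A `gait_cohort` from [make_cohort()], or a list with
#'   elements `seq`, `bout` and optional `annotations` per item.
#' @param config Pipeline configuration.
#' @param use_annotations Also run the manual-annotation path when
#'   annotations are available (default `TRUE`).
#' @return List with `features`, `events`, `exclusions`, `diagnostics`.
#' @export
run_extract <- function(cohort, config = default_config(),
                        use_annotations = TRUE) {
  items <- if (inherits(cohort, "gait_cohort")) cohort$walks else cohort
  feats <- list()
  events <- list()
  excl <- list()
  diags <- list()
  for (w in items) {
    ann <- if (use_annotations) w$annotations else NULL
    r <- extract_bout(w$seq, w$bout, ann, config)
    if (!is.null(r$features)) feats[[length(feats) + 1L]] <- r$features
    if (!is.null(r$events)) events[[length(events) + 1L]] <- r$events
    if (!is.null(r$exclusions)) excl[[length(excl) + 1L]] <- r$exclusions
    diags[[length(diags) + 1L]] <- r$diagnostics
  }
  list(features = if (length(feats)) do.call(rbind, feats) else NULL,
       events = if (length(events)) do.call(rbind, events) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL,
       diagnostics = diags)
}

#' Run the concurrent-validity analysis
#'
#' Given the extracted features table and the reference (ground-truth)
#' table, produces the full-sample correlation report, the capped
#' (reference steps <= `max_steps`) report, the step-count cutoff sweep,
#' difference metrics for the directly comparable features, and -- when
#' paired ON/OFF treatment states are present -- Wilcoxon signed-rank
#' comparisons per feature.
#'
#' @param features Features table from [run_extract()].
#' @param truth Reference table keyed by `bout_id` (e.g. `cohort$truth`).
#' @param config Pipeline configuration.
#' @return List with `report_all`, `report_capped`, `cap_exclusions`,
#'   `sweep`, `differences`, and optionally `on_off`.
#' @export
run_validity <- function(features, truth, config = default_config()) {
  if (is.null(features) || !nrow(features)) {
    stop("no features to analyse", call. = FALSE)
  }
  factor <- config$stats$bonferroni_factor
  report_all <- validity_report(features, truth, factor = factor)
  ref_steps <- setNames(truth$n_steps, truth$bout_id)
  capped <- filter_bouts(features, ref_steps,
                         min_steps = config$features$min_steps,
                         max_steps = config$features$max_steps)
  report_capped <- if (nrow(capped)) {
    validity_report(capped, truth, factor = factor)
  } else {
    NULL
  }
  auto <- features[features$annotation_method == "auto", ]
  sweep <- if (nrow(auto) >= 3) {
    cutoff_sweep(auto$n_steps, ref_steps[auto$bout_id],
                 config$stats$cutoffs)
  } else {
    NULL
  }
  ri <- match(features$bout_id, truth$bout_id)
  comparable <- intersect(c("n_steps", "cadence", "step_time_cv",
                            "step_width_cv"), names(truth))
  diffs <- lapply(setNames(nm = comparable), function(f)
    difference_metrics(features[[f]], truth[[f]][ri]))
  out <- list(report_all = report_all, report_capped = report_capped,
              cap_exclusions = attr(capped, "exclusions"), sweep = sweep,
              differences = diffs)
  if (all(c("ON", "OFF") %in% features$treatment_state)) {
    on <- features[features$treatment_state == "ON", ]
    off <- features[features$treatment_state == "OFF", ]
    key <- intersect(paste(on$subject_id, on$annotation_method),
                     paste(off$subject_id, off$annotation_method))
    oi <- match(key, paste(on$subject_id, on$annotation_method))
    fi <- match(key, paste(off$subject_id, off$annotation_method))
    featcols <- intersect(c("n_steps", "cadence", "step_width_mean",
                            "step_width_cv", "step_time_cv"), names(on))
    out$on_off <- do.call(rbind, lapply(featcols, function(f) {
      r <- tryCatch(wilcoxon_signed_rank(on[[f]][oi], off[[f]][fi]),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(feature = f, W = r$W, p = r$p, n = r$n_effective,
                 method = r$method)
    }))
  }
  out
}
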