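PIPELINE_STAGES <- c("preprocess", "tuning", "dynamics", "granger", "lmm")

#' Pipeline configuration
#'
#' All tunable analysis parameters in one validated object. Unknown fields
#' are rejected, and the object round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param likelihood_threshold Pose likelihood below which frames are
#'   interpolated (default 0.9).
#' @param speed_floor Log2-speed floor epsilon in cm/s (default 0.25).
#' @param stationary_threshold Stationary speed cutoff in cm/s (default 3).
#' @param stationary_fraction Strict stationary-session threshold (2/3).
#' @param frame_rate Video frame rate in Hz.
#' @param sample_interval_s Scatter decimation interval in seconds.
#' @param bin_width_speed Speed-bin width in cm/s.
#' @param bin_width_logspeed Log2-speed bin width.
#' @param min_count Minimum points per reported tuning bin.
#' @param window_max_s Largest moving-average window in seconds (grid runs
#'   from one frame to this value in one-frame steps).
#' @param reference_window_s Window at which light/dark correlations are
#'   compared (1.3 s, the cohort optimum).
#' @param gc_minutes Granger segment length in minutes.
#' @param gc_p_max Largest VAR order for selection.
#' @param gc_order Fixed VAR order (`NULL` = select by AIC).
#' @param lmm_method `"REML"` or `"ML"`.
#' @param stages Character vector of enabled stages (subset of
#'   `preprocess`, `tuning`, `dynamics`, `granger`, `lmm`).
#' @param seed Integer seed recorded in output provenance.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(likelihood_threshold = 0.9,
                            speed_floor = 0.25,
                            stationary_threshold = 3,
                            stationary_fraction = 2 / 3,
                            frame_rate = 30,
                            sample_interval_s = 1,
                            bin_width_speed = 1,
                            bin_width_logspeed = 0.1,
                            min_count = 5,
                            window_max_s = 10,
                            reference_window_s = 1.3,
                            gc_minutes = 5,
                            gc_p_max = 30,
                            gc_order = NULL,
                            lmm_method = "REML",
                            stages = PIPELINE_STAGES,
                            seed = 1L) {
  cfg <- list(likelihood_threshold = likelihood_threshold,
              speed_floor = speed_floor,
              stationary_threshold = stationary_threshold,
              stationary_fraction = stationary_fraction,
              frame_rate = frame_rate,
              sample_interval_s = sample_interval_s,
              bin_width_speed = bin_width_speed,
              bin_width_logspeed = bin_width_logspeed,
              min_count = min_count,
              window_max_s = window_max_s,
              reference_window_s = reference_window_s,
              gc_minutes = gc_minutes,
              gc_p_max = gc_p_max,
              gc_order = gc_order,
              lmm_method = lmm_method,
              stages = stages,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stopf("unknown pipeline_config field(s): %s", paste(unknown, collapse = ", "))
  }
  assert_scalar_num(cfg$likelihood_threshold, "likelihood_threshold", 0, 1)
  assert_scalar_num(cfg$speed_floor, "speed_floor", lower = 1e-9)
  assert_scalar_num(cfg$stationary_threshold, "stationary_threshold", lower = 0)
  assert_scalar_num(cfg$stationary_fraction, "stationary_fraction", 0, 1)
  assert_scalar_num(cfg$window_max_s, "window_max_s", lower = 1 / cfg$frame_rate)
  if (!all(cfg$stages %in% PIPELINE_STAGES)) {
    stopf("stages must be a subset of %s", paste(PIPELINE_STAGES, collapse = ", "))
  }
  if (!cfg$lmm_method %in% c("REML", "ML")) stopf("lmm_method must be REML or ML")
  cfg
}

#' Write a pipeline configuration to YAML
#' @param cfg A [pipeline_config()].
#' @param path Output file.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stopf("unknown key(s) in pipeline config: %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

# md5 of the canonical YAML rendering; used for output provenance.
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Validate a cohort's input files
#'
#' Checks, per manifest row, that the photometry, pose and labels files
#' parse; that photometry timestamps are strictly increasing (offending row
#' numbers are reported); that the pose and label frame counts match the TTL
#' frame count; and that TTL times fall inside the recording. Problems are
#' reported, never thrown.
#'
#' @param manifest A manifest data.frame (see [read_manifest()]).
#' @return A data.frame of violations (`session_id`, `check`, `detail`);
#'   zero rows when everything is well-formed.
#' @export
validate_inputs <- function(manifest) {
  v <- list()
  note <- function(sid, check, detail) {
    v[[length(v) + 1L]] <<- data.frame(session_id = sid, check = check,
                                       detail = detail, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$session_id[i]
    raw <- tryCatch(read_photometry_csv(manifest$photometry_path[i]),
                    error = function(e) e)
    if (inherits(raw, "error")) {
      d <- tryCatch(utils::read.csv(manifest$photometry_path[i]),
                    error = function(e) NULL)
      if (!is.null(d) && "time_s" %in% names(d)) {
        bad <- which(diff(d$time_s) <= 0)
        if (length(bad)) {
          note(sid, "non_monotone_time",
               sprintf("rows %s", paste(utils::head(bad + 1L, 10), collapse = ",")))
        } else {
          note(sid, "photometry_unreadable", conditionMessage(raw))
        }
      } else {
        note(sid, "photometry_unreadable", conditionMessage(raw))
      }
      raw <- NULL
    }
    pose <- tryCatch(read_pose_csv(manifest$pose_path[i]), error = function(e) e)
    if (inherits(pose, "error")) {
      note(sid, "pose_unreadable", conditionMessage(pose))
      pose <- NULL
    }
    labels <- tryCatch(read_labels_csv(manifest$labels_path[i]),
                       error = function(e) e)
    if (inherits(labels, "error")) {
      note(sid, "labels_unreadable", conditionMessage(labels))
      labels <- NULL
    }
    if (!is.null(raw)) {
      n_ttl <- length(raw$ttl_frame_times)
      if (!is.null(pose) && nrow(pose) != n_ttl) {
        note(sid, "pose_frame_mismatch",
             sprintf("%d pose frames vs %d TTL frames", nrow(pose), n_ttl))
      }
      if (!is.null(labels) && nrow(labels) != n_ttl) {
        note(sid, "labels_frame_mismatch",
             sprintf("%d label frames vs %d TTL frames", nrow(labels), n_ttl))
      }
    }
  }
  if (!length(v)) {
    return(data.frame(session_id = character(0), check = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Run the end-to-end analysis pipeline over a cohort
#'
#' Per-session preprocessing (photometry correction, kinematics, alignment)
#' followed by the enabled cohort analyses: tuning curves and fits, window
#' scans with light/dark comparison, per-animal Granger causality, and the
#' mixed-effects models. Results are written as CSV/JSON under
#' `out_dir/<stage>/`, each stage with a `provenance.json` recording the
#' configuration hash and seed; re-running with unchanged inputs reproduces
#' identical outputs. Per-session failures are isolated, reported, and
#' raised together at the end.
#'
#' @param config A [pipeline_config()].
#' @param manifest A manifest data.frame with file paths.
#' @param out_dir Output directory.
#' @return (Invisibly) a list with `sessions` (stacked aligned data), the
#'   stage results, and `failures`.
#' @export
run_pipeline <- function(config, manifest, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = hash, seed = config$seed,
               package = as.character(utils::packageVersion("cholspeed")))
  stage_dir <- function(stage) {
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    jsonlite::write_json(prov, file.path(d, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    d
  }
  failures <- character(0)
  parts <- list()
  d_pre <- stage_dir("preprocess")
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$session_id[i]
    res <- tryCatch({
      raw <- read_photometry_csv(manifest$photometry_path[i])
      pose <- read_pose_csv(manifest$pose_path[i],
                            frame_rate = config$frame_rate)
      labels <- read_labels_csv(manifest$labels_path[i],
                                frame_rate = config$frame_rate)
      dff <- process_photometry(raw)
      pose_i <- interpolate_low_likelihood(pose, config$likelihood_threshold)
      sp <- neck_speed(pose_i, frame_rate = config$frame_rate,
                       epsilon = config$speed_floor,
                       stationary_threshold = config$stationary_threshold)
      aligned <- align_session(dff, sp, labels,
                               animal_id = manifest$animal_id[i],
                               session_id = sid,
                               lighting = manifest$lighting[i])
      if ("preprocess" %in% config$stages) {
        utils::write.csv(
          data.frame(frame = aligned$frame, time_s = aligned$time_s,
                     dff = aligned$dff, zdff = aligned$zdff,
                     speed_cm_s = aligned$speed, logspeed = aligned$logspeed,
                     stationary = as.integer(aligned$stationary)),
          file.path(d_pre, paste0(sid, ".csv")), row.names = FALSE)
        jsonlite::write_json(
          list(alpha = attr(dff, "alpha"), beta = attr(dff, "beta"),
               poly_coeffs = attr(dff, "poly_coeffs"),
               config_hash = hash, seed = config$seed),
          file.path(d_pre, paste0(sid, ".json")), auto_unbox = TRUE,
          digits = NA)
      }
      aligned
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", sid, conditionMessage(res)))
    } else {
      parts[[sid]] <- res
    }
  }
  if (!length(parts)) stopf("all sessions failed:\n%s",
                            paste(failures, collapse = "\n"))
  cohort <- do.call(rbind, parts)
  rownames(cohort) <- NULL
  class(cohort) <- c("aligned_session", "data.frame")
  out <- list(sessions = cohort, failures = failures)

  sids <- unique(cohort$session_id)
  by_session <- lapply(sids, function(s) cohort[cohort$session_id == s, ])
  names(by_session) <- sids
  lighting_of <- vapply(by_session, function(s) s$lighting[1], "")

  if ("tuning" %in% config$stages) {
    d <- stage_dir("tuning")
    curves <- lapply(by_session, function(s) {
      ss <- sample_interval(s, config$sample_interval_s)
      bin_tuning_curve(ss$logspeed, ss$zdff, config$bin_width_logspeed,
                       config$min_count)
    })
    agg <- aggregate_curves(curves, conditions = lighting_of)
    utils::write.csv(agg, file.path(d, "logspeed_tuning.csv"), row.names = FALSE)
    fits <- lapply(by_session, function(s) {
      ss <- sample_interval(s, config$sample_interval_s)
      lin <- fit_linear_log(ss$logspeed, ss$zdff)
      ex <- tryCatch(fit_saturating_exponential(ss$speed, ss$zdff),
                     error = function(e) NULL)
      list(linear = lin, exponential = ex)
    })
    jsonlite::write_json(c(list(provenance = prov), fits),
                         file.path(d, "fits.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    out$tuning <- list(curves = curves, aggregate = agg, fits = fits)
  }

  if ("dynamics" %in% config$stages) {
    d <- stage_dir("dynamics")
    grid <- seq(1 / config$frame_rate, config$window_max_s,
                by = 1 / config$frame_rate)
    scans <- lapply(sids, function(s) {
      ses <- by_session[[s]]
      window_scan(ses$zdff, ses$logspeed, grid, config$frame_rate, s)
    })
    names(scans) <- sids
    long <- do.call(rbind, lapply(scans, function(sc) {
      data.frame(session_id = sc$session_id, window_s = sc$window_s, r = sc$r)
    }))
    utils::write.csv(long, file.path(d, "window_scans.csv"), row.names = FALSE)
    summ <- if (length(scans) >= 2) cohort_window_summary(scans) else NULL
    cmp <- NULL
    sl <- scans[lighting_of == "light"]
    sd_ <- scans[lighting_of == "dark"]
    if (length(sl) >= 2 && length(sd_) >= 2) {
      cmp <- compare_light_dark(sl, sd_, config$reference_window_s)
    }
    jsonlite::write_json(
      list(provenance = prov,
           optimal_window_per_session = lapply(scans, function(sc)
             sc$optimal_window),
           peak_window = summ$peak_window,
           tests = if (!is.null(cmp))
             cmp[c("t", "df", "p_t", "ks_stat", "p_ks")]),
      file.path(d, "summary.json"), auto_unbox = TRUE, digits = NA)
    out$dynamics <- list(scans = scans, summary = summ, light_dark = cmp)
  }

  if ("granger" %in% config$stages) {
    d <- stage_dir("granger")
    gc <- per_mouse_gc(cohort, p = config$gc_order, p_max = config$gc_p_max,
                       minutes = config$gc_minutes,
                       frame_rate = config$frame_rate)
    utils::write.csv(gc$per_animal, file.path(d, "gc_per_animal.csv"),
                     row.names = FALSE)
    utils::write.csv(gc$per_session, file.path(d, "gc_per_session.csv"),
                     row.names = FALSE)
    out$granger <- gc
  }

  if ("lmm" %in% config$stages) {
    d <- stage_dir("lmm")
    models <- list()
    if (length(unique(cohort$animal_id)) >= 2) {
      models$speed_dark <- tryCatch(
        suppressWarnings(fit_lmm(build_design(cohort, "speed_dark"),
                                 config$lmm_method)),
        error = function(e) e)
      stat <- stationary_session_filter(cohort, config$stationary_fraction)
      if (nrow(stat) && length(unique(stat$animal_id)) >= 2) {
        models$stationary_speed_dark <- tryCatch(
          suppressWarnings(fit_lmm(build_design(stat, "stationary_speed_dark"),
                                   config$lmm_method)),
          error = function(e) e)
      }
      if (!is.null(out$granger)) {
        models$gc_direction_dark <- tryCatch(
          suppressWarnings(fit_lmm(build_design(out$granger$per_session,
                                                "gc_direction_dark"),
                                   config$lmm_method)),
          error = function(e) e)
      }
      if (!all(is.na(cohort$state))) {
        models$behavior_speed_dark <- tryCatch(
          suppressWarnings(fit_lmm(build_design(cohort, "behavior_speed_dark"),
                                   config$lmm_method)),
          error = function(e) e)
      }
    }
    skipped <- character(0)
    for (nm in names(models)) {
      if (inherits(models[[nm]], "error")) {
        # a cohort too small/degenerate for one of the models is reported,
        # not fatal: the remaining stages and models stand on their own
        warnf("lmm model '%s' skipped: %s", nm, conditionMessage(models[[nm]]))
        skipped <- c(skipped, nm)
        models[[nm]] <- NULL
        next
      }
      utils::write.csv(models[[nm]]$coefficients,
                       file.path(d, paste0(nm, "_coefficients.csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        c(list(provenance = prov), as.list(models[[nm]]$stats)),
        file.path(d, paste0(nm, "_stats.json")), auto_unbox = TRUE,
        digits = NA)
    }
    out$lmm <- models
    out$lmm_skipped <- skipped
  }

  out$failures <- failures
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(failures)) {
    stopf("pipeline completed with failures:\n%s",
          paste(failures, collapse = "\n"))
  }
  invisible(out)
}
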