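#' Simulate one complete synthetic session
#'
#' Chains the generator stages: behavior labels, trajectory and pose track,
#' tracking-derived neck speed (interpolated at the same likelihood threshold
#' the analysis side uses), latent cholinergic trace, and rendered raw
#' photometry. The latent is driven by the *measured* (tracking-derived)
#' speed, so the configured regression coefficients are defined with respect
#' to the kinematics the analysis will actually compute.
#'
#' @param config A [synth_config()].
#' @param animal_id,session_id Identifiers stored in the session metadata.
#' @param lighting `"light"` or `"dark"`.
#' @param seed Integer seed; stage seeds are derived deterministically.
#' @param animal_effects Optional `c(intercept=, slope=)` animal-level
#'   deviations shared across a cohort's sessions.
#' @return A list of class `synth_session`: `raw` ([raw_photometry()]),
#'   `pose` (written pose track, with jitter and dropouts), `labels`,
#'   `latent`, `truth` (ground truth incl. `speed_true`), and `meta`.
#' @export
simulate_session <- function(config, animal_id = "m1", session_id = "s1",
                             lighting = "light", seed = config$seed,
                             animal_effects = NULL) {
  labels <- simulate_behavior(config, seed = derive_seed(seed, 1))
  traj <- simulate_trajectory(labels, config, seed = derive_seed(seed, 2))
  pose_i <- interpolate_low_likelihood(traj$pose, threshold = 0.9)
  sp <- neck_speed(pose_i, frame_rate = config$frame_rate,
                   epsilon = config$speed_floor)
  latent <- simulate_latent(sp$speed, labels, config, lighting = lighting,
                            seed = derive_seed(seed, 3),
                            animal_effects = animal_effects)
  rp <- render_photometry(latent, config, seed = derive_seed(seed, 4))
  truth <- rp$truth
  truth$speed_true <- traj$speed_true
  truth$speed_measured <- sp$speed
  truth$animal_effects <- attr(latent, "animal_effects")
  truth$session_effects <- attr(latent, "session_effects")
  structure(
    list(raw = rp$raw, pose = traj$pose, labels = labels, latent = latent,
         truth = truth,
         meta = list(animal_id = animal_id, session_id = session_id,
                     lighting = lighting, seed = seed)),
    class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("<synth_session> %s/%s (%s), %d frames, %d photometry samples\n",
              x$meta$animal_id, x$meta$session_id, x$meta$lighting,
              nrow(x$labels), length(x$raw$time_s)))
  invisible(x)
}

#' Process a synthetic session through the analysis pipeline
#'
#' Runs the photometry correction and kinematics stages on a generated
#' session and joins them into one frame-aligned table.
#'
#' @param session A `synth_session`.
#' @param likelihood_threshold Pose likelihood threshold (default 0.9).
#' @param epsilon Log-speed floor in cm/s (defaults to the generator's).
#' @return An aligned-session data.frame (see [align_session()]).
#' @export
process_session <- function(session, likelihood_threshold = 0.9,
                            epsilon = NULL) {
  cfg_eps <- epsilon %||% session$meta$epsilon %||% 0.25
  dff <- process_photometry(session$raw)
  pose_i <- interpolate_low_likelihood(session$pose, likelihood_threshold)
  fr <- attr(session$pose, "frame_rate") %||% 30
  sp <- neck_speed(pose_i, frame_rate = fr, epsilon = cfg_eps)
  align_session(dff, sp, session$labels,
                animal_id = session$meta$animal_id,
                session_id = session$meta$session_id,
                lighting = session$meta$lighting)
}

#' Join frame-aligned photometry, kinematics and behavior into one table
#'
#' @param dff A `dff_trace` from [process_photometry()].
#' @param speed A `speed_series` from [neck_speed()].
#' @param labels A `behavior_labels` data.frame (optional; `NULL` fills the
#'   behavior columns with `NA`).
#' @param animal_id,session_id,lighting Session metadata.
#' @return A data.frame of class `aligned_session` with columns `animal_id`,
#'   `session_id`, `lighting`, `frame`, `time_s`, `dff`, `zdff`, `speed`,
#'   `logspeed`, `stationary`, `state`, `community`.
#' @export
align_session <- function(dff, speed, labels = NULL, animal_id = "m1",
                          session_id = "s1", lighting = "light") {
  n <- nrow(dff)
  if (nrow(speed) != n) {
    stopf("photometry frames (%d) and pose frames (%d) differ", n, nrow(speed))
  }
  if (!is.null(labels) && nrow(labels) != n) {
    stopf("labels (%d frames) not aligned with photometry (%d frames)",
          nrow(labels), n)
  }
  out <- data.frame(
    animal_id = animal_id, session_id = session_id, lighting = lighting,
    frame = dff$frame, time_s = dff$time_s, dff = dff$dff, zdff = dff$zdff,
    speed = speed$speed, logspeed = speed$logspeed,
    stationary = speed$stationary,
    state = if (is.null(labels)) NA_character_ else labels$state,
    community = if (is.null(labels)) NA_integer_ else labels$community,
    row.names = NULL
  )
  class(out) <- c("aligned_session", "data.frame")
  out
}

resolve_lighting <- function(schedule, animal, j) {
  if (is.function(schedule)) return(schedule(animal, j))
  if (length(schedule) > 1L) return(schedule[[min(j, length(schedule))]])
  switch(schedule,
         alternate = if (j %% 2L == 1L) "light" else "dark",
         light = "light",
         dark = "dark",
         stopf("unknown lighting schedule '%s'", schedule))
}

#' Simulate a cohort of sessions, optionally writing files
#'
#' Draws per-animal random effects once per animal and simulates every
#' session deterministically from the base seed. With `dir` given, writes the
#' photometry CSV, DeepLabCut-dialect pose CSV, labels CSV, a frame-level
#' ground-truth CSV plus JSON sidecar per session, and the cohort manifest;
#' identical `(config, seed)` produce byte-identical files.
#'
#' @param config A [synth_config()].
#' @param n_animals Number of animals.
#' @param sessions_per_animal Scalar or length-`n_animals` vector.
#' @param lighting_schedule `"alternate"` (default), `"light"`, `"dark"`, a
#'   character vector indexed by session number, or `function(animal, j)`.
#' @param seed Base integer seed.
#' @param dir Output directory (created); `NULL` keeps everything in memory.
#' @param keep_sessions If `TRUE`, returns the simulated `synth_session`
#'   objects (memory-heavy for long sessions).
#' @return A list with `manifest` (data.frame; includes file paths when `dir`
#'   is given) and, if requested, `sessions`.
#' @export
simulate_cohort <- function(config, n_animals = 2, sessions_per_animal = 2,
                            lighting_schedule = "alternate",
                            seed = config$seed, dir = NULL,
                            keep_sessions = is.null(dir)) {
  if (n_animals < 1) stopf("n_animals must be >= 1")
  ns <- rep_len(sessions_per_animal, n_animals)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  sessions <- list()
  for (a in seq_len(n_animals)) {
    animal_id <- sprintf("m%02d", a)
    eff <- with_seed(derive_seed(seed, a, 0), c(
      intercept = stats::rnorm(1, 0, config$ranef_sd$animal_intercept),
      slope = stats::rnorm(1, 0, config$ranef_sd$animal_slope)))
    for (j in seq_len(ns[a])) {
      session_id <- sprintf("%s_s%03d", animal_id, j)
      lighting <- resolve_lighting(lighting_schedule, a, j)
      sess <- simulate_session(config, animal_id, session_id, lighting,
                               seed = derive_seed(seed, a, j),
                               animal_effects = eff)
      row <- data.frame(animal_id = animal_id, session_id = session_id,
                        lighting = lighting, photometry_path = NA_character_,
                        pose_path = NA_character_, labels_path = NA_character_,
                        stringsAsFactors = FALSE)
      if (!is.null(dir)) {
        pp <- file.path(dir, paste0(session_id, "_photometry.csv"))
        sp <- file.path(dir, paste0(session_id, "_pose.csv"))
        lp <- file.path(dir, paste0(session_id, "_labels.csv"))
        write_photometry_csv(sess$raw, pp)
        write_pose_dlc(sess$pose, sp)
        write_labels_csv(sess$labels, lp)
        gt <- file.path(dir, paste0(session_id, "_truth.csv"))
        utils::write.csv(data.frame(
          frame = sess$labels$frame,
          drive = sess$truth$drive_frames,
          dff_true = sess$truth$dff_true_frames,
          speed_true = sess$truth$speed_true), gt, row.names = FALSE)
        jsonlite::write_json(
          list(coeffs = sess$truth$coeffs,
               animal_effects = as.list(sess$truth$animal_effects),
               session_effects = as.list(sess$truth$session_effects),
               lighting = lighting, seed = sess$meta$seed),
          file.path(dir, paste0(session_id, "_truth.json")),
          auto_unbox = TRUE, digits = NA)
        row$photometry_path <- pp
        row$pose_path <- sp
        row$labels_path <- lp
      }
      rows[[length(rows) + 1L]] <- row
      if (keep_sessions) sessions[[session_id]] <- sess
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    # the on-disk manifest uses paths relative to its own directory, so a
    # cohort directory is relocatable and identical seeds give identical bytes
    rel <- manifest
    for (col in c("photometry_path", "pose_path", "labels_path")) {
      rel[[col]] <- basename(rel[[col]])
    }
    write_manifest(rel, file.path(dir, "manifest.csv"))
  }
  out <- list(manifest = manifest)
  if (keep_sessions) out$sessions <- sessions
  out
}

#' Simulate a cohort and run each session through the analysis pipeline
#'
#' Streaming driver for recovery studies: each session is simulated, its raw
#' photometry corrected and z-scored, its pose converted to speed, and only
#' the frame-aligned table is kept.
#'
#' @inheritParams simulate_cohort
#' @return One stacked `aligned_session` data.frame for the whole cohort.
#' @export
simulate_aligned_cohort <- function(config, n_animals = 2,
                                    sessions_per_animal = 2,
                                    lighting_schedule = "alternate",
                                    seed = config$seed) {
  ns <- rep_len(sessions_per_animal, n_animals)
  parts <- vector("list", sum(ns))
  k <- 0L
  for (a in seq_len(n_animals)) {
    eff <- with_seed(derive_seed(seed, a, 0), c(
      intercept = stats::rnorm(1, 0, config$ranef_sd$animal_intercept),
      slope = stats::rnorm(1, 0, config$ranef_sd$animal_slope)))
    for (j in seq_len(ns[a])) {
      sess <- simulate_session(config, sprintf("m%02d", a),
                               sprintf("m%02d_s%03d", a, j),
                               resolve_lighting(lighting_schedule, a, j),
                               seed = derive_seed(seed, a, j),
                               animal_effects = eff)
      k <- k + 1L
      parts[[k]] <- process_session(sess, epsilon = config$speed_floor)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("aligned_session", "data.frame")
  out
}
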