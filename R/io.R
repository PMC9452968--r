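# Readers and writers for the on-disk session formats:
#   photometry CSV  time_s,f470,f405,ttl   (ttl = 1 at each video-frame edge)
#   pose CSV        DeepLabCut dialect (3 header rows) or simplified dialect
#   labels CSV      frame,community        (0 run, 1 walk, 2 groom, 3 rear, 4 still)
#   manifest CSV    animal_id,session_id,lighting,photometry_path,pose_path,labels_path

DLC_BODYPARTS <- c("neck", "nose", "left_ear", "right_ear", "tail_base", "tail_tip")

#' Write a photometry session to CSV
#'
#' @param raw A [raw_photometry()].
#' @param path Output file.
#' @export
write_photometry_csv <- function(raw, path) {
  ttl <- integer(length(raw$time_s))
  ttl[findInterval(raw$ttl_frame_times, raw$time_s)] <- 1L
  utils::write.csv(
    data.frame(time_s = raw$time_s, f470 = raw$f470, f405 = raw$f405, ttl = ttl),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a photometry session from CSV
#'
#' @param path File written by [write_photometry_csv()].
#' @return A [raw_photometry()]; frame times are the rising edges of the TTL
#'   column.
#' @export
read_photometry_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "f470", "f405", "ttl")
  if (!all(need %in% names(d))) {
    stopf("photometry file %s lacks columns %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  }
  edges <- which(diff(c(0L, d$ttl)) == 1L)
  raw_photometry(d$time_s, d$f470, d$f405, d$time_s[edges])
}

#' Write a pose track in the DeepLabCut CSV dialect
#'
#' Three header rows (scorer / bodyparts / coords) and x,y,likelihood columns
#' for neck, nose, left/right ear, tail base and tail tip. Bodyparts other
#' than the neck are placed at fixed offsets from the neck (only the neck is
#' used downstream).
#'
#' @param pose A `pose_track` data.frame.
#' @param path Output file.
#' @param scorer Scorer name written in the first header row.
#' @export
write_pose_dlc <- function(pose, path, scorer = "synth") {
  off <- list(neck = c(0, 0), nose = c(2, 0), left_ear = c(1, 1),
              right_ear = c(1, -1), tail_base = c(-3, 0), tail_tip = c(-7, 0))
  cols <- lapply(DLC_BODYPARTS, function(bp) {
    cbind(pose$neck_x + off[[bp]][1], pose$neck_y + off[[bp]][2],
          pose$likelihood)
  })
  mat <- do.call(cbind, cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, ncol(mat))), collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(DLC_BODYPARTS, each = 3)), collapse = ","), con)
  writeLines(paste(c("coords", rep(c("x", "y", "likelihood"),
                                   length(DLC_BODYPARTS))), collapse = ","), con)
  utils::write.table(cbind(pose$frame, round(mat, 6)), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DeepLabCut-dialect pose CSV
#'
#' @param path File with the 3-row scorer/bodyparts/coords header.
#' @param frame_rate Frame rate used to reconstruct `time_s`.
#' @param bodypart Bodypart to extract (default `"neck"`).
#' @return A `pose_track` data.frame.
#' @export
read_pose_dlc <- function(path, frame_rate = 30, bodypart = "neck") {
  hdr <- readLines(path, n = 3)
  parts <- strsplit(hdr[2], ",")[[1]]
  coords <- strsplit(hdr[3], ",")[[1]]
  sel <- which(parts == bodypart)
  if (length(sel) < 3L) stopf("bodypart '%s' not found in %s", bodypart, path)
  d <- utils::read.csv(path, skip = 3, header = FALSE)
  xi <- sel[coords[sel] == "x"][1]
  yi <- sel[coords[sel] == "y"][1]
  li <- sel[coords[sel] == "likelihood"][1]
  frame <- as.integer(d[[1]])
  out <- data.frame(frame = frame, time_s = frame / frame_rate,
                    neck_x = d[[xi]], neck_y = d[[yi]], likelihood = d[[li]],
                    row.names = NULL)
  class(out) <- c("pose_track", "data.frame")
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Write a pose track in the simplified dialect
#'
#' Columns `frame,time_s,neck_x,neck_y,likelihood`.
#'
#' @inheritParams write_pose_dlc
#' @export
write_pose_simple <- function(pose, path) {
  utils::write.csv(
    data.frame(frame = pose$frame, time_s = pose$time_s,
               neck_x = pose$neck_x, neck_y = pose$neck_y,
               likelihood = pose$likelihood),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a pose CSV in either dialect
#'
#' Detects the DeepLabCut 3-row header by its leading `scorer` cell and
#' falls back to the simplified `frame,time_s,neck_x,neck_y,likelihood`
#' dialect.
#'
#' @inheritParams read_pose_dlc
#' @return A `pose_track` data.frame.
#' @export
read_pose_csv <- function(path, frame_rate = 30) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "scorer")) return(read_pose_dlc(path, frame_rate))
  d <- utils::read.csv(path)
  need <- c("frame", "time_s", "neck_x", "neck_y", "likelihood")
  if (!all(need %in% names(d))) {
    stopf("pose file %s lacks columns %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  }
  class(d) <- c("pose_track", "data.frame")
  attr(d, "frame_rate") <- frame_rate
  d
}

#' Write per-frame behavior community labels
#'
#' @param labels A `behavior_labels` data.frame.
#' @param path Output file.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(data.frame(frame = labels$frame, community = labels$community),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read per-frame behavior community labels
#'
#' @param path File with columns `frame,community`.
#' @param frame_rate Frame rate used to reconstruct `time_s`.
#' @return A `behavior_labels` data.frame.
#' @export
read_labels_csv <- function(path, frame_rate = 30) {
  d <- utils::read.csv(path)
  if (!all(c("frame", "community") %in% names(d))) {
    stopf("labels file %s lacks frame,community columns", path)
  }
  short <- COMMUNITY_STATE[d$community + 1L]
  out <- data.frame(frame = as.integer(d$frame),
                    time_s = as.integer(d$frame) / frame_rate,
                    state = names(STATE_SHORT)[match(short, STATE_SHORT)],
                    community = as.integer(d$community),
                    row.names = NULL)
  class(out) <- c("behavior_labels", "data.frame")
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Write a cohort manifest
#'
#' @param manifest Data.frame with columns `animal_id`, `session_id`,
#'   `lighting`, `photometry_path`, `pose_path`, `labels_path`.
#' @param path Output file.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Relative file paths are resolved against the manifest's own directory.
#'
#' @param path Manifest CSV.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "session_id", "lighting", "photometry_path",
            "pose_path", "labels_path")
  if (!all(need %in% names(m))) {
    stopf("manifest lacks columns: %s",
          paste(setdiff(need, names(m)), collapse = ", "))
  }
  base <- dirname(path)
  for (col in c("photometry_path", "pose_path", "labels_path")) {
    rel <- !file.exists(m[[col]]) & file.exists(file.path(base, m[[col]]))
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m
}
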