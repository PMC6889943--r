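.SESSION_COLS <- c("frame_idx", "t_s", "cup_found", "cup_x_mm", "cup_y_mm",
                   "ball_found", "ball_x_mm", "ball_y_mm",
                   "cup_px_x", "cup_px_y", "ball_px_x", "ball_px_y")

#' Write a tracked session to CSV
#'
#' Plain CSV in the session schema (`frame_idx, t_s, cup_found, cup_x_mm,
#' cup_y_mm, ball_found, ball_x_mm, ball_y_mm, cup_px_x, cup_px_y,
#' ball_px_x, ball_px_y`). Missing values are written as empty fields,
#' never as zeros. A comment header records the absolute session start
#' time when known, so recordings can be aligned with external clocks.
#'
#' @param series A `track_series` or data frame with the schema columns.
#' @param path Output file.
#' @param start_time Optional absolute session start (POSIXct or string).
#' @return The path, invisibly.
#' @export
write_session <- function(series, path, start_time = NULL) {
  df <- as.data.frame(series)
  missing_cols <- setdiff(.SESSION_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing session columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, c(.SESSION_COLS, setdiff(names(df), .SESSION_COLS))]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(start_time))
    writeLines(sprintf("# session_start: %s", format(start_time)), con)
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tracked session from CSV
#'
#' Inverse of [write_session()]: schema fields round-trip losslessly,
#' empty fields become NA, extra columns are preserved. Malformed rows
#' (wrong field count or non-numeric values in numeric columns) raise an
#' error naming the offending line numbers.
#'
#' @param path Session CSV.
#' @param board A [board_spec()] attached to the result.
#' @return A `track_series` data frame.
#' @export
read_session <- function(path, board = board_spec()) {
  if (!file.exists(path)) stop("session file not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  if (length(body) < 1) stop("empty session file: ", path)
  nfield <- lengths(regmatches(body, gregexpr(",", body, fixed = TRUE))) + 1
  bad <- which(nfield != nfield[1])
  if (length(bad) > 0)
    stop("malformed session rows at line(s): ",
         paste(which(!is_comment)[bad], collapse = ", "))
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SESSION_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing session columns: ", paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.SESSION_COLS, c("cup_found", "ball_found"))
  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value in column %s at data row(s): %s",
                     cc, paste(bad, collapse = ", ")))
      df[[cc]] <- conv
    } else {
      df[[cc]] <- as.numeric(v)   # all-empty columns read back as logical
    }
  }
  df$frame_idx <- as.integer(df$frame_idx)
  df$cup_found <- as.logical(df$cup_found)
  df$ball_found <- as.logical(df$ball_found)
  hdr <- grep("^# session_start:", lines, value = TRUE)
  attr(df, "board") <- board
  attr(df, "fps") <- if (nrow(df) > 1) 1 / median(diff(df$t_s)) else NA_real_
  if (length(hdr) > 0)
    attr(df, "session_start") <- sub("^# session_start: *", "", hdr[1])
  class(df) <- c("track_series", "data.frame")
  df
}

#' Write / read a task file
#'
#' Plain-text YAML encoding of a [task_spec()].
#'
#' @param task A `task_spec`.
#' @param path File path.
#' @return `read_task` returns a `task_spec`.
#' @export
write_task <- function(task, path) {
  obj <- list(kind = task$kind, level = task$level,
              go_cues = as.numeric(task$go_cues),
              targets = lapply(task$targets, function(tg)
                list(cx_mm = tg$cx_mm, cy_mm = tg$cy_mm, r_mm = tg$r_mm)))
  if (!is.null(task$fig8))
    obj$fig8 <- list(c1 = as.numeric(task$fig8$c1),
                     c2 = as.numeric(task$fig8$c2),
                     r_mm = task$fig8$r_mm)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_task
#' @export
read_task <- function(path) {
  if (!file.exists(path)) stop("task file not found: ", path)
  obj <- yaml::read_yaml(path)
  fig8 <- NULL
  if (!is.null(obj$fig8)) {
    ctr <- (unlist(obj$fig8$c1) + unlist(obj$fig8$c2)) / 2
    ax <- unlist(obj$fig8$c1) - ctr
    fig8 <- figure8_template(ctr, 2 * obj$fig8$r_mm, ax)
  }
  task_spec(kind = obj$kind,
            targets = lapply(obj$targets, function(tg)
              target_circle(tg$cx_mm, tg$cy_mm, tg$r_mm)),
            go_cues = as.numeric(unlist(obj$go_cues)),
            level = obj$level, fig8 = fig8)
}

#' Write / read a model parameter file
#'
#' Plain-text key/value (YAML) encoding of [cupball_params()].
#'
#' @param params A `cupball_params`.
#' @param path File path.
#' @return `read_params` returns a `cupball_params`.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path, precision = 17)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  do.call(cupball_params, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a recorded session
#'
#' The end-to-end workflow: load the registration, track the video,
#' compute the task metrics, optionally verify the tracked trajectory
#' against a reference recording, and write the session CSV, results CSV,
#' a JSON report and a per-stage log (frames decoded, dropped, cup-found
#' rate). Stage failures abort with the stage named.
#'
#' @param video Frame source for [track_video()].
#' @param registration Path to a registration file, or a list
#'   `(map, board)`.
#' @param task Path to a task file, or a [task_spec()].
#' @param out_dir Output directory.
#' @param profiles Colour profiles (default [default_profiles()]).
#' @param params Optional [cupball_params()] for ball-margin estimation.
#' @param reference Optional reference session (path or data frame with
#'   `t_s`, `cup_x_mm`, `cup_y_mm`) for verification.
#' @param fs,fc Verification resampling rate and filter cutoff, Hz.
#' @return List with `session`, `metrics`, `verification` (or NULL),
#'   `log`; files are written under `out_dir`.
#' @export
run_pipeline <- function(video, registration, task, out_dir,
                         profiles = default_profiles(), params = NULL,
                         reference = NULL, fs = 100, fc = 6) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  reg <- stage("registration", {
    if (is.character(registration)) read_registration(registration)
    else registration
  })
  task <- stage("task", {
    if (is.character(task)) read_task(task) else task
  })
  series <- stage("tracking",
                  track_video(video, reg$map, profiles$cup, profiles$ball,
                              board = reg$board))
  metrics <- stage("metrics", session_metrics(series, task, params = params))
  verification <- NULL
  if (!is.null(reference)) {
    verification <- stage("verification", {
      ref <- if (is.character(reference)) read_session(reference) else reference
      ok <- series$cup_found
      compare_trajectories(ref$t_s, cbind(ref$cup_x_mm, ref$cup_y_mm),
                           series$t_s[ok],
                           cbind(series$cup_x_mm[ok], series$cup_y_mm[ok]),
                           fs = fs, fc = fc)
    })
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage("output", {
    write_session(series, file.path(out_dir, "session.csv"))
    write.csv(metrics, file.path(out_dir, "results.csv"), row.names = FALSE)
    log <- list(frames_decoded = nrow(series),
                frames_dropped = length(attr(series, "dropped_frames")),
                cup_found_rate = mean(series$cup_found),
                ball_found_rate = mean(series$ball_found),
                n_trials = nrow(metrics))
    report <- list(log = log)
    if (!is.null(verification))
      report$verification <- list(
        lag_samples = verification$lag_samples,
        scale = verification$scale,
        rotation_deg = atan2(verification$rotation[2, 1],
                             verification$rotation[1, 1]) * 180 / pi,
        translation_mm = as.numeric(verification$translation),
        mse_mm = verification$mse_mm, rmse_mm = verification$rmse_mm,
        r = verification$r)
    writeLines(.to_json(report), file.path(out_dir, "report.json"))
    writeLines(c(sprintf("frames decoded: %d", log$frames_decoded),
                 sprintf("frames dropped: %d", log$frames_dropped),
                 sprintf("cup found rate: %.4f", log$cup_found_rate),
                 sprintf("ball found rate: %.4f", log$ball_found_rate),
                 sprintf("trials: %d", log$n_trials)),
               file.path(out_dir, "pipeline.log"))
    log
  }) -> log
  list(session = series, metrics = metrics, verification = verification,
       log = log)
}

## Minimal JSON serializer for report lists (numbers, strings, vectors,
## nested lists).
.to_json <- function(x, indent = "") {
  if (is.list(x)) {
    items <- vapply(names(x), function(nm)
      sprintf("%s  \"%s\": %s", indent, nm,
              .to_json(x[[nm]], paste0(indent, "  "))), character(1))
    sprintf("{\n%s\n%s}", paste(items, collapse = ",\n"), indent)
  } else if (is.character(x)) {
    if (length(x) == 1) sprintf("\"%s\"", x)
    else sprintf("[%s]", paste(sprintf("\"%s\"", x), collapse = ", "))
  } else {
    v <- ifelse(is.na(x), "null", format(x, digits = 12))
    if (length(x) == 1) v else sprintf("[%s]", paste(v, collapse = ", "))
  }
}
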