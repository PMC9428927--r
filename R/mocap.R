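# Comparison of empirical joint-angle traces (e.g. optoelectronic motion
# capture of hip angles during walking) against an osteologically viable
# pose envelope. Sign conventions match the ACS: flexion (+fe), extension
# (-fe), abduction (+abad), adduction (-abad), external rotation (+lar).

#' Joint-angle trace
#'
#' @param frames data.frame with columns `time` (s, strictly increasing),
#'   `fe`, `abad`, `lar` (degrees).
#' @param condition label (e.g. substrate / speed).
#' @export
joint_angle_trace <- function(frames, condition = "unlabelled") {
  frames <- as.data.frame(frames)
  need <- c("time", "fe", "abad", "lar")
  if (!all(need %in% names(frames)))
    stop("trace needs columns: ", paste(need, collapse = ", "))
  frames <- frames[, need]
  if (nrow(frames) < 1) stop("empty trace")
  if (!all(vapply(frames, function(c) all(is.finite(c)), TRUE)))
    stop("non-finite values in trace")
  if (nrow(frames) > 1 && any(diff(frames$time) <= 0))
    stop("time must be strictly increasing")
  structure(list(frames = frames, condition = as.character(condition)),
            class = "joint_angle_trace")
}

#' @export
print.joint_angle_trace <- function(x, ...) {
  cat(sprintf("<joint_angle_trace '%s': %d frames, %.2f s>\n", x$condition,
              nrow(x$frames), diff(range(x$frames$time))))
  invisible(x)
}

#' Load a joint-angle trace from CSV
#'
#' Expects a header with `time`, `fe`, `abad`, `lar` (degrees) and an
#' optional `condition` column.
#'
#' @param path CSV path.
#' @return a [joint_angle_trace()].
#' @export
load_trace <- function(path) {
  df <- read.csv(path, comment.char = "#")
  cond <- if ("condition" %in% names(df)) as.character(df$condition[1]) else
    sub("\\.[^.]*$", "", basename(path))
  joint_angle_trace(df, condition = cond)
}

#' Save a joint-angle trace to CSV
#' @param trace a [joint_angle_trace()].
#' @param path output path.
#' @export
save_trace <- function(trace, path) {
  df <- trace$frames
  df$condition <- trace$condition
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

snap_to_grid <- function(x, step, lo, hi) {
  # nearest multiple of step; ties broken toward zero
  s <- x / step
  snapped <- sign(s) * ceiling(abs(s) - 0.5) * step
  in_range <- snapped >= lo - 1e-9 & snapped <= hi + 1e-9
  snapped[!in_range] <- NA
  snapped
}

#' Test a trace against a viable-pose envelope
#'
#' Each frame is snapped to the nearest grid pose (per axis; ties toward
#' zero) and is viable iff that grid pose is viable in the map. Frames
#' outside the grid ranges are unviable and flagged.
#'
#' @param trace a [joint_angle_trace()].
#' @param map a `rom_map` from [classify_poses()].
#' @return a `viability_report`: per-frame data.frame (snapped pose, viable,
#'   in_range), `fraction_viable`, and `excursions` (contiguous runs of
#'   unviable frames as first/last frame indices).
#' @export
trace_viability <- function(trace, map) {
  stopifnot(inherits(trace, "joint_angle_trace"), inherits(map, "rom_map"))
  fr <- trace$frames
  if (nrow(fr) == 0) stop("empty trace")
  g <- map$grid
  ax <- grid_axis_values(g)
  sa <- snap_to_grid(fr$abad, g$step, g$abad_range[1], g$abad_range[2])
  sf <- snap_to_grid(fr$fe, g$step, g$fe_range[1], g$fe_range[2])
  sl <- snap_to_grid(fr$lar, g$step, g$lar_range[1], g$lar_range[2])
  in_range <- !is.na(sa) & !is.na(sf) & !is.na(sl)
  # index into the abad-outer / fe / lar-inner pose ordering
  ia <- round((sa - g$abad_range[1]) / g$step) + 1
  ife <- round((sf - g$fe_range[1]) / g$step) + 1
  il <- round((sl - g$lar_range[1]) / g$step) + 1
  idx <- ((ia - 1) * length(ax$fe) + (ife - 1)) * length(ax$lar) + il
  viable <- rep(FALSE, nrow(fr))
  viable[in_range] <- map$viable[idx[in_range]]
  runs <- rle(!viable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  exc <- data.frame(first_frame = starts[runs$values],
                    last_frame = ends[runs$values])
  structure(list(
    frames = data.frame(time = fr$time, fe = fr$fe, abad = fr$abad,
                        lar = fr$lar, snapped_abad = sa, snapped_fe = sf,
                        snapped_lar = sl, in_range = in_range,
                        viable = viable),
    fraction_viable = mean(viable),
    excursions = exc,
    condition = trace$condition),
    class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat(sprintf("<viability_report '%s': %.1f%% of %d frames viable, %d excursion(s)>\n",
              x$condition, 100 * x$fraction_viable, nrow(x$frames),
              nrow(x$excursions)))
  invisible(x)
}

#' Write a viability report (CSV + JSON summary sidecar)
#' @param report a `viability_report`.
#' @param path CSV output path.
#' @export
write_viability_report <- function(report, path) {
  write.csv(report$frames, path, row.names = FALSE)
  jsonlite::write_json(
    list(condition = report$condition,
         fraction_viable = report$fraction_viable,
         n_frames = nrow(report$frames),
         n_excursions = nrow(report$excursions)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
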