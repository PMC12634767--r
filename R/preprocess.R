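#' Raw cyclic recordings
#'
#' A raw recording is one continuous angle signal for one observation:
#' strictly increasing sample times (seconds) and the flexion-extension
#' angle (degrees).
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param angle numeric vector of angles in degrees, same length as `time`.
#' @param id observation label.
#' @return object of class `"raw_recording"`.
#' @export
raw_recording <- function(time, angle, id = "obs") {
  time <- as.numeric(time); angle <- as.numeric(angle)
  if (length(time) != length(angle))
    stop("time and angle must have equal length")
  if (length(time) < 3L) stop("recording too short")
  if (anyNA(time) || anyNA(angle)) stop("missing values in recording '", id, "'")
  if (any(diff(time) <= 0)) stop("sample times must be strictly increasing")
  structure(list(time = time, angle = angle, id = as.character(id)),
            class = "raw_recording")
}

#' Read raw recordings from a long-format CSV
#'
#' Columns `id, time_s, angle_deg`, multiple rows per id.
#'
#' @param path CSV file path.
#' @return named list of [raw_recording()] objects, in order of first
#'   appearance.
#' @export
read_raw_recordings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time_s", "angle_deg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("raw recording CSV missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(as.character(df$id))
  recs <- lapply(ids, function(i) {
    sub <- df[df$id == i, ]
    raw_recording(sub$time_s, sub$angle_deg, id = i)
  })
  names(recs) <- ids
  recs
}

# Indices of local minima of x whose prominence (height to the lower of the
# two enclosing maxima) is at least `prominence`.
local_minima <- function(x, prominence) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) > 0) + 1L   # strict local minima
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left until a sample lower than x[i] (or the edge); the highest
    # point seen bounds the left prominence, same on the right
    left <- x[seq_len(i - 1L)]
    below_l <- which(left < x[i])
    lo_l <- if (length(below_l)) max(below_l) + 1L else 1L
    prom_l <- max(left[lo_l:(i - 1L)], x[i]) - x[i]
    right <- x[(i + 1L):n]
    below_r <- which(right < x[i])
    hi_r <- if (length(below_r)) min(below_r) - 1L else length(right)
    prom_r <- if (hi_r >= 1L) max(right[seq_len(hi_r)], x[i]) - x[i] else 0
    keep[k] <- min(prom_l, prom_r) >= prominence
  }
  cand[keep]
}

#' Divide a recording into complete flexion-extension cycles
#'
#' Cycles are delimited minimum-to-minimum of the angle signal (maximum
#' flexion as the cycle boundary), using local minima with prominence at
#' least `min_prominence`.  Segments are half-open index ranges
#' `[start, end)`; consecutive segments share their boundary minimum.
#'
#' @param rec a [raw_recording()].
#' @param min_prominence prominence threshold in degrees; default 20% of
#'   the recording's angle range.
#' @return data.frame with columns `start`, `end` (sample indices of the
#'   delimiting minima) and `duration` (seconds), one row per complete
#'   cycle in temporal order.
#' @export
segment_cycles <- function(rec, min_prominence = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  rng <- diff(range(rec$angle))
  if (is.null(min_prominence)) min_prominence <- 0.2 * rng
  mins <- if (rng > 0) local_minima(rec$angle, min_prominence) else integer(0)
  if (length(mins) < 4L)
    stop("recording '", rec$id, "': found ", max(0L, length(mins) - 1L),
         " complete cycles; need at least 3 so the first and last can be ",
         "discarded")
  data.frame(start = mins[-length(mins)],
             end = mins[-1L],
             duration = rec$time[mins[-1L]] - rec$time[mins[-length(mins)]])
}

#' Discard the first and last cycles of a recording
#'
#' The edge cycles of a continuous cyclic record are transient (movement
#' onset and stopping) and are dropped before averaging.
#'
#' @param segments cycle segment data.frame from [segment_cycles()].
#' @return the segments minus the first and last rows.
#' @export
discard_edge_cycles <- function(segments) {
  if (nrow(segments) < 3L)
    stop("need at least 3 cycles to discard the first and last, got ",
         nrow(segments))
  segments[-c(1L, nrow(segments)), , drop = FALSE]
}

#' Time-normalize one cycle onto the common grid
#'
#' The angle samples of the segment are interpolated with a cubic spline
#' (FMM end conditions) and resampled at the grid points mapped linearly
#' onto the segment's time span, so every cycle lives on normalized time
#' \[0, 1\].
#'
#' @param rec a [raw_recording()].
#' @param seg one row of the segment data.frame (list/data.frame with
#'   `start` and `end`).
#' @param grid a [time_grid()].
#' @return numeric vector of length `length(grid)`.
#' @export
normalize_cycle <- function(rec, seg, grid) {
  i0 <- seg$start[1L]; i1 <- seg$end[1L]
  if (i1 <= i0) stop("invalid segment: end <= start")
  idx <- i0:i1
  if (length(idx) < 4L)
    stop("segment has ", length(idx), " samples; cubic spline needs >= 4")
  tt <- rec$time[idx]; aa <- rec$angle[idx]
  f <- stats::splinefun(tt, aa, method = "fmm")
  f(tt[1L] + as.numeric(grid) * (tt[length(tt)] - tt[1L]))
}

#' Pointwise mean of curves on a common grid
#'
#' @param curves list of numeric vectors (or a matrix with one curve per
#'   row), all on the same grid.
#' @return numeric vector, the pointwise arithmetic mean.
#' @export
average_cycles <- function(curves) {
  if (is.matrix(curves)) curves <- asplit(curves, 1L)
  if (!length(curves)) stop("no curves to average")
  K <- length(curves[[1L]])
  if (any(vapply(curves, length, 1L) != K))
    stop("curves are not on a common grid (unequal lengths)")
  colMeans(do.call(rbind, lapply(curves, as.numeric)))
}

#' Preprocess one raw recording into its mean cycle curve
#'
#' Runs the full preprocessing chain: segment into cycles, discard the
#' first and last, time-normalize each retained cycle onto `grid`, and
#' average them pointwise.
#'
#' @param rec a [raw_recording()].
#' @param grid a [time_grid()].
#' @param min_prominence passed to [segment_cycles()].
#' @return list with `curve` (numeric K-vector), `mean_duration` (seconds,
#'   mean cycle duration of the retained cycles) and `n_cycles`.
#' @export
preprocess_recording <- function(rec, grid = time_grid(100L),
                                 min_prominence = NULL) {
  segs <- segment_cycles(rec, min_prominence)
  segs <- discard_edge_cycles(segs)
  curves <- lapply(seq_len(nrow(segs)),
                   function(r) normalize_cycle(rec, segs[r, ], grid))
  list(curve = average_cycles(curves),
       mean_duration = mean(segs$duration),
       n_cycles = nrow(segs))
}

#' Preprocess a set of recordings into a curve set
#'
#' @param recs list of [raw_recording()] objects.
#' @param grid a [time_grid()].
#' @param min_prominence passed to [segment_cycles()].
#' @return list with `curves` (an angle [curve_set()]) and `durations`
#'   (named numeric, per-observation mean cycle duration in seconds).
#' @export
preprocess_recordings <- function(recs, grid = time_grid(100L),
                                  min_prominence = NULL) {
  out <- lapply(recs, preprocess_recording, grid = grid,
                min_prominence = min_prominence)
  vals <- do.call(rbind, lapply(out, `[[`, "curve"))
  ids <- vapply(recs, `[[`, "", "id")
  list(curves = curve_set(vals, grid, "angle", ids = ids),
       durations = stats::setNames(vapply(out, `[[`, 0, "mean_duration"), ids))
}

#' Differentiate curves with respect to real time
#'
#' Each curve is represented by a cubic spline on normalized time s and
#' differentiated analytically; the chain rule d/dt = (1/duration) d/ds
#' converts to real time, so units advance deg -> deg/s -> deg/s2.
#'
#' @param cs a [curve_set()] with response `"angle"` (yielding velocity) or
#'   `"velocity"` (yielding acceleration).
#' @param durations numeric vector of per-observation cycle durations in
#'   seconds (recycled if length 1); named vectors are matched to
#'   observation ids.
#' @return a [curve_set()] of the derivative response on the same grid.
#' @export
differentiate_curves <- function(cs, durations) {
  stopifnot(is_curve_set(cs))
  if (cs$response == "acceleration")
    stop("cannot differentiate beyond acceleration")
  if (missing(durations) || is.null(durations) || anyNA(durations))
    stop("per-observation cycle durations (seconds) are required")
  n <- nrow(cs$values)
  if (!is.null(names(durations)) && length(durations) == n) {
    miss <- setdiff(cs$ids, names(durations))
    if (length(miss))
      stop("no duration for observation(s): ", paste(miss, collapse = ", "))
    durations <- durations[cs$ids]
  }
  durations <- rep_len(as.numeric(durations), n)
  if (any(durations <= 0)) stop("durations must be positive")
  s <- as.numeric(cs$grid)
  d1 <- t(vapply(seq_len(n), function(i) {
    f <- stats::splinefun(s, cs$values[i, ], method = "fmm")
    f(s, deriv = 1L) / durations[i]
  }, numeric(length(s))))
  curve_set(d1, cs$grid,
            response = if (cs$response == "angle") "velocity" else "acceleration",
            ids = cs$ids)
}
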