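#' Vector-magnitude cut points for minute classification
#'
#' Per-minute triaxial vector-magnitude thresholds: moderate-to-vigorous
#' physical activity (MVPA) at >= 2690 counts/min and light activity at
#' >= 200 counts/min. Everything below 200 is sedentary+nonwear. The three
#' classes tile the whole count range: sedentary [0, 200), light
#' [200, 2690), MVPA [2690, Inf).
#'
#' @param mvpa_lo lower bound of MVPA (counts/min).
#' @param light_lo lower bound of light activity (counts/min).
#' @return list of class \code{"cut_points"}.
#' @export
cut_points <- function(mvpa_lo = 2690, light_lo = 200) {
  if (!(0 < light_lo && light_lo < mvpa_lo))
    stop("need 0 < light_lo < mvpa_lo")
  structure(list(mvpa_lo = mvpa_lo, light_lo = light_lo),
            class = "cut_points")
}

# validate an epoch stream and return its epoch length in seconds
stream_epoch_s <- function(stream) {
  need <- c("timestamp", "axis1", "axis2", "axis3", "steps")
  miss <- setdiff(need, names(stream))
  if (length(miss)) stop("stream missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(stream) < 2L) return(NA_real_)
  dt <- as.numeric(diff(stream$timestamp), units = "secs")
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    stop("epochs must be equally spaced; found gaps of ",
         paste(unique(round(dt, 3))[1:min(3, length(unique(dt)))],
               collapse = ", "), " s")
  dt[1]
}

#' Crop a count stream to a measurement window
#'
#' Retains epochs with \code{start <= timestamp < end} (half-open window),
#' e.g. the start and end of the DLW measurement period.
#'
#' @param stream data.frame with columns \code{timestamp} (POSIXct),
#'   \code{axis1}, \code{axis2}, \code{axis3}, \code{steps}.
#' @param start,end POSIXct window bounds, \code{start < end}.
#' @return the cropped stream (warns if empty).
#' @export
crop_to_window <- function(stream, start, end) {
  stream_epoch_s(stream)
  if (!(start < end)) stop("start must precede end")
  out <- stream[stream$timestamp >= start & stream$timestamp < end, ,
                drop = FALSE]
  if (nrow(out) == 0L) warning("cropping left no epochs in the window")
  rownames(out) <- NULL
  out
}

#' Reintegrate a count stream to a longer epoch
#'
#' Sums counts and steps within non-overlapping windows of the target length,
#' aligned to the first epoch of the stream. The target must be an integer
#' multiple of the source epoch (default: 10-s epochs to 60-s epochs, the
#' unit on which the cut points are defined). Totals are conserved exactly
#' when the stream length is a multiple of the window; a trailing partial
#' window is kept (as a shorter sum) so conservation always holds.
#'
#' @inheritParams crop_to_window
#' @param target_s target epoch length in seconds (default 60).
#' @return stream with one row per target window, timestamped at the window
#'   start.
#' @export
reintegrate <- function(stream, target_s = 60) {
  src <- stream_epoch_s(stream)
  if (is.na(src)) src <- target_s
  if (target_s %% src != 0)
    stop("target epoch (", target_s, " s) must be an integer multiple of the ",
         "source epoch (", src, " s)")
  k <- target_s / src
  grp <- (seq_len(nrow(stream)) - 1L) %/% k
  sum_by <- function(v) as.numeric(tapply(v, grp, sum))
  data.frame(
    timestamp = stream$timestamp[!duplicated(grp)],
    axis1 = sum_by(stream$axis1),
    axis2 = sum_by(stream$axis2),
    axis3 = sum_by(stream$axis3),
    steps = sum_by(stream$steps)
  )
}

#' Triaxial vector magnitude
#'
#' Euclidean norm of the three axis counts, \eqn{\sqrt{a_1^2+a_2^2+a_3^2}}.
#'
#' @param axis1,axis2,axis3 numeric vectors of per-epoch counts; or a stream
#'   data.frame as first argument.
#' @return numeric vector of vector magnitudes.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(axis1, axis2 = NULL, axis3 = NULL) {
  if (is.data.frame(axis1)) {
    s <- axis1
    return(sqrt(s$axis1^2 + s$axis2^2 + s$axis3^2))
  }
  sqrt(axis1^2 + axis2^2 + axis3^2)
}

#' Mark wear time on a minute stream
#'
#' Standard zero-run rule: a run of at least \code{window_min} consecutive
#' minutes of zero vector magnitude is non-wear. Short bursts of nonzero
#' minutes (a "spike" of up to \code{spike_tol} consecutive minutes) inside
#' an otherwise-zero stretch do not interrupt the run and are themselves
#' marked non-wear when the merged run qualifies.
#'
#' @param minute_stream 60-s epoch stream (see [reintegrate()]).
#' @param window_min minimum non-wear run length in minutes (default 90).
#' @param spike_tol maximum length of a nonzero spike absorbed into a zero
#'   run (default 2 minutes).
#' @return logical vector, TRUE where the minute is worn.
#' @export
mark_wear <- function(minute_stream, window_min = 90, spike_tol = 2) {
  stream_epoch_s(minute_stream)
  vm <- vector_magnitude(minute_stream)
  n <- length(vm)
  if (n == 0L) return(logical(0))
  zero <- vm == 0
  # absorb nonzero spikes of length <= spike_tol flanked by zeros on both sides
  r <- rle(zero)
  if (length(r$lengths) > 2L) {
    ends <- cumsum(r$lengths)
    for (j in seq_along(r$lengths)[-c(1L, length(r$lengths))]) {
      if (!r$values[j] && r$lengths[j] <= spike_tol &&
          r$values[j - 1L] && r$values[j + 1L]) {
        zero[(ends[j] - r$lengths[j] + 1L):ends[j]] <- TRUE
      }
    }
  }
  wear <- rep(TRUE, n)
  r2 <- rle(zero)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  for (j in seq_along(r2$lengths)) {
    if (r2$values[j] && r2$lengths[j] >= window_min)
      wear[starts[j]:ends[j]] <- FALSE
  }
  wear
}

#' Classify minutes into activity classes
#'
#' Applies the vector-magnitude cut points per minute: MVPA at
#' \code{>= mvpa_lo}, light at \code{[light_lo, mvpa_lo)}, sedentary+nonwear
#' below \code{light_lo}. The partition is exhaustive and exclusive.
#'
#' @param minute_stream 60-s epoch stream.
#' @param cuts a [cut_points()].
#' @return factor with levels \code{sedentary_nonwear}, \code{light},
#'   \code{mvpa}, one per minute.
#' @export
classify_minutes <- function(minute_stream, cuts = cut_points()) {
  stream_epoch_s(minute_stream)
  vm <- vector_magnitude(minute_stream)
  cls <- ifelse(vm >= cuts$mvpa_lo, "mvpa",
                ifelse(vm >= cuts$light_lo, "light", "sedentary_nonwear"))
  factor(cls, levels = c("sedentary_nonwear", "light", "mvpa"))
}

#' Daily activity summaries and participant means
#'
#' Totals steps and minutes per activity class by calendar day (day boundary
#' at local midnight, timezone-naive timestamps) and averages the daily
#' values over days with any wear. Wear flags are reported alongside the
#' class minutes (worn minutes per day); non-wear minutes remain inside the
#' sedentary+nonwear class rather than being removed from it.
#'
#' @param minute_stream 60-s epoch stream.
#' @param cuts a [cut_points()].
#' @param wear optional logical vector from [mark_wear()]; computed with
#'   default parameters when NULL.
#' @return list with \code{days} (data.frame: \code{date}, \code{steps},
#'   \code{sed_nonwear_min}, \code{light_min}, \code{mvpa_min},
#'   \code{worn_min}) and \code{means} (one-row data.frame of daily means
#'   over days with any wear, plus \code{n_days}).
#' @export
summarize_days <- function(minute_stream, cuts = cut_points(), wear = NULL) {
  stream_epoch_s(minute_stream)
  if (is.null(wear)) wear <- mark_wear(minute_stream)
  if (length(wear) != nrow(minute_stream))
    stop("wear flags must match the stream length")
  cls <- classify_minutes(minute_stream, cuts)
  date <- as.Date(minute_stream$timestamp)
  days <- data.frame(
    date = sort(unique(date)),
    steps = as.numeric(tapply(minute_stream$steps, date, sum)),
    sed_nonwear_min = as.numeric(tapply(cls == "sedentary_nonwear", date, sum)),
    light_min = as.numeric(tapply(cls == "light", date, sum)),
    mvpa_min = as.numeric(tapply(cls == "mvpa", date, sum)),
    worn_min = as.numeric(tapply(wear, date, sum))
  )
  keep <- days$worn_min > 0
  if (!any(keep)) {
    warning("no days with any wear time; empty summary")
    means <- days[0, -1]
  } else {
    means <- as.data.frame(as.list(colMeans(days[keep, -1])))
    means$n_days <- sum(keep)
  }
  list(days = days, means = means)
}
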