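# Contraction-event detection from projected-area time series, and
# contraction rates per observation interval.

#' Contraction-detector configuration
#'
#' @param smooth_k Running-median width in samples (odd; default 5).
#' @param baseline_window_s Width of the rolling baseline window in
#'   seconds (default 2 h).
#' @param baseline_quantile Quantile of the smoothed area taken as the
#'   expanded-state baseline (default 0.9).
#' @param theta_sub Relative area drop below baseline that opens an
#'   event (default 0.1).
#' @param theta_full Relative drop beyond which an event is a full-body
#'   contraction rather than a sub-contraction (default 0.5).
#' @param merge_gap_s Events separated by less than this gap are merged
#'   (default 5 min).
#' @return Configuration list.
#' @export
contraction_config <- function(smooth_k = 5L, baseline_window_s = 7200,
                               baseline_quantile = 0.9, theta_sub = 0.1,
                               theta_full = 0.5, merge_gap_s = 300) {
  stopifnot(smooth_k >= 1, smooth_k %% 2 == 1, baseline_window_s > 0,
            baseline_quantile > 0, baseline_quantile <= 1,
            theta_sub > 0, theta_full > theta_sub, merge_gap_s >= 0)
  list(smooth_k = as.integer(smooth_k),
       baseline_window_s = baseline_window_s,
       baseline_quantile = baseline_quantile, theta_sub = theta_sub,
       theta_full = theta_full, merge_gap_s = merge_gap_s)
}

.empty_events <- function() {
  data.frame(start_s = numeric(0), trough_s = numeric(0),
             end_s = numeric(0), amplitude = numeric(0),
             class = character(0), stringsAsFactors = FALSE)
}

# running median tolerant of missing values: NAs are bridged by linear
# interpolation for smoothing only, then restored
.smooth_area <- function(t, a, k) {
  if (k <= 1 || sum(!is.na(a)) < 2) return(a)
  filled <- stats::approx(t[!is.na(a)], a[!is.na(a)], xout = t,
                          rule = 2)$y
  sm <- stats::runmed(filled, k, endrule = "median")
  sm[is.na(a)] <- NA_real_
  sm
}

#' Detect contraction events in an area trace
#'
#' The trace is smoothed with a running median; a rolling
#' high-quantile baseline tracks the expanded-state area; events are
#' maximal intervals where the normalized area drops below
#' `1 - theta_sub`, merged across short gaps, and classed `full_body`
#' when the trough drops below `1 - theta_full` (otherwise `sub`).
#' Missing samples never seed or extend an event.
#'
#' @param trace Data.frame with columns `timestamp_s` (strictly
#'   increasing, seconds) and `area` (or `area_px` / `area_mm2`);
#'   missing areas are `NA`.
#' @param config A [contraction_config()].
#' @return Data.frame with columns `start_s`, `trough_s`, `end_s`,
#'   `amplitude` (relative drop, in \[0, 1\]) and `class`.
#' @export
detect_contractions <- function(trace, config = contraction_config()) {
  a_col <- intersect(c("area", "area_px", "area_mm2"), names(trace))[1]
  if (is.na(a_col)) stop("trace has no area column")
  t <- trace$timestamp_s
  a <- trace[[a_col]]
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (all(is.na(a))) return(.empty_events())
  if (diff(range(t)) < config$baseline_window_s)
    stop("trace shorter than the baseline window")
  sm <- .smooth_area(t, a, config$smooth_k)
  half <- config$baseline_window_s / 2
  n <- length(t)
  dt <- diff(t)
  regular <- max(dt) - min(dt) < 1e-9
  win_q <- function(w) {
    if (all(is.na(w))) NA_real_
    else stats::quantile(w, config$baseline_quantile, na.rm = TRUE,
                         names = FALSE)
  }
  baseline <- if (regular) {
    hk <- as.integer(floor(half / dt[1]))
    vapply(seq_len(n), function(i)
      win_q(sm[max(1L, i - hk):min(n, i + hk)]), numeric(1))
  } else {
    vapply(seq_len(n), function(i)
      win_q(sm[t >= t[i] - half & t <= t[i] + half]), numeric(1))
  }
  norm <- sm / baseline
  below <- !is.na(norm) & norm < 1 - config$theta_sub
  if (!any(below)) return(.empty_events())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by a short gap
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap <- t[runs$i0[k]] - t[merged$i1[nrow(merged)]]
      if (gap < config$merge_gap_s)
        merged$i1[nrow(merged)] <- runs$i1[k]
      else merged <- rbind(merged, runs[k, ])
    }
  }
  ev <- lapply(seq_len(nrow(merged)), function(k) {
    idx <- merged$i0[k]:merged$i1[k]
    tr <- idx[which.min(norm[idx])]
    amp <- 1 - min(norm[idx], na.rm = TRUE)
    data.frame(start_s = t[merged$i0[k]], trough_s = t[tr],
               end_s = t[merged$i1[k]], amplitude = amp,
               class = if (min(norm[idx], na.rm = TRUE) <
                           1 - config$theta_full) "full_body" else "sub",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, ev)
}

#' Contraction rate over an interval
#'
#' @param events Data.frame from [detect_contractions()].
#' @param interval Numeric `c(start_s, end_s)` with positive length;
#'   events are counted by their start time.
#' @param class_filter Optional event class (`"full_body"` or `"sub"`)
#'   to count; default counts all.
#' @return Events per day.
#' @export
contraction_rate <- function(events, interval, class_filter = NULL) {
  stopifnot(length(interval) == 2L)
  dur <- interval[2] - interval[1]
  if (!is.finite(dur) || dur <= 0) stop("interval must have positive length")
  ev <- events
  if (!is.null(class_filter))
    ev <- ev[ev$class == class_filter, , drop = FALSE]
  n <- sum(ev$start_s >= interval[1] & ev$start_s < interval[2])
  n / (dur / 86400)
}
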