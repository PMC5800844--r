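# Respirometry: rolling oxygen-uptake rates from dissolved-O2 traces and
# the contraction-phase uptake contrast.

#' Rolling oxygen-uptake rate
#'
#' Least-squares slope of O2 against time in a centered rolling window,
#' reported with the uptake sign convention: positive when O2 declines.
#'
#' @param o2 Data.frame with columns `timestamp_s` and `o2_uM`.
#' @param window Window width in samples (>= 3).
#' @return Data.frame (`timestamp_s`, `uptake_uM_per_hr`); positions
#'   whose window would run off either end carry `NA`.
#' @export
respiration_rate <- function(o2, window = 9L) {
  stopifnot(all(c("timestamp_s", "o2_uM") %in% names(o2)))
  n <- nrow(o2)
  if (window < 3L) stop("window must be at least 3 samples")
  if (window > n) stop("window (", window, ") larger than trace (", n, ")")
  half <- (window - 1L) %/% 2L
  t_hr <- o2$timestamp_s / 3600
  y <- o2$o2_uM
  rate <- rep(NA_real_, n)
  for (i in (half + 1L):(n - (window - 1L - half))) {
    idx <- (i - half):(i - half + window - 1L)
    tt <- t_hr[idx] - mean(t_hr[idx])
    rate[i] <- -sum(tt * (y[idx] - mean(y[idx]))) / sum(tt^2)
  }
  data.frame(timestamp_s = o2$timestamp_s, uptake_uM_per_hr = rate)
}

#' Contraction-phase versus expanded-phase oxygen uptake
#'
#' Labels each uptake sample as inside or outside a contraction event,
#' contrasts the phase means, and assesses the contrast against a null
#' built by circularly shifting the phase labels (preserving their run
#' structure) a seeded number of times.
#'
#' @param rates Data.frame from [respiration_rate()].
#' @param events Data.frame from
#'   [detect_contractions()] (columns `start_s`, `end_s`); at least one
#'   event is required.
#' @param n_shuffles Number of circular shifts (default 999).
#' @param seed Integer seed.
#' @return List: `mean_contracting`, `mean_expanded`, `difference`
#'   (contracting minus expanded), `p_value`.
#' @export
phase_coupled_uptake <- function(rates, events, n_shuffles = 999,
                                 seed = 1) {
  if (is.null(events) || nrow(events) == 0L)
    stop("no contraction events: phase contrast undefined")
  ok <- !is.na(rates$uptake_uM_per_hr)
  t <- rates$timestamp_s[ok]
  u <- rates$uptake_uM_per_hr[ok]
  inside <- rep(FALSE, length(t))
  for (k in seq_len(nrow(events)))
    inside <- inside | (t >= events$start_s[k] & t <= events$end_s[k])
  if (!any(inside) || all(inside))
    stop("events cover none or all of the uptake trace")
  contrast <- function(lab) mean(u[lab]) - mean(u[!lab])
  obs <- contrast(inside)
  n <- length(t)
  null <- .with_seed(seed, {
    shifts <- sample.int(n - 1L, n_shuffles, replace = TRUE)
    vapply(shifts, function(s) {
      lab <- inside[((seq_len(n) - 1L + s) %% n) + 1L]
      contrast(lab)
    }, numeric(1))
  })
  list(mean_contracting = mean(u[inside]),
       mean_expanded = mean(u[!inside]),
       difference = obs,
       p_value = (1 + sum(abs(null) >= abs(obs))) / (n_shuffles + 1))
}
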