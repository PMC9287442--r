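# Trace preprocessing, spike removal, teleportation-aligned averaging,
# delta-Vm statistics, behavioural hit rate, and nonparametric tests.

#' Preprocess a membrane-potential trace
#'
#' Optional zero-phase low-pass filtering (4th-order Butterworth applied
#' forward and backward), resampling by linear interpolation, and removal of
#' slow trends. Trends slower than `highpass` are estimated with a zero-phase
#' centred running mean of window `1/highpass` seconds and subtracted; when
#' the window exceeds the trace length the trend reduces to the best-fitting
#' straight line, which removes reference drifts without phase distortion.
#'
#' @param trace A `vm_trace`.
#' @param lowpass Low-pass cutoff (Hz), or `NULL` to skip. Must be below the
#'   Nyquist frequency of the trace.
#' @param resample_to Output sampling rate (Hz), or `NULL` to keep the input rate.
#' @param highpass High-pass (slow-trend removal) cutoff (Hz), or `NULL` to skip.
#'
#' @return A `vm_trace` at the output sampling rate.
#' @export
#' @examples
#' tl <- generate_session_timeline(4, seed = 1)
#' tr <- generate_vm_trace(vm_generator_spec(seed = 1), tl)
#' pre <- preprocess_trace(tr, lowpass = 100, highpass = 1e-5)
preprocess_trace <- function(trace, lowpass = NULL, resample_to = NULL,
                             highpass = NULL) {
  stopifnot(inherits(trace, "vm_trace"))
  v <- trace$samples
  fs <- trace$sampling_rate
  if (!is.null(lowpass)) {
    if (lowpass >= fs / 2) {
      stop(sprintf("`lowpass` (%g Hz) must be below the Nyquist frequency (%g Hz)",
                   lowpass, fs / 2))
    }
    bf <- signal::butter(4, lowpass / (fs / 2), type = "low")
    v <- signal::filtfilt(bf, v)
  }
  if (!is.null(resample_to) && resample_to != fs) {
    t_old <- (seq_along(v) - 1) / fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / resample_to)
    v <- approx(t_old, v, xout = t_new)$y
    fs <- resample_to
  }
  if (!is.null(highpass)) {
    trend <- slow_trend(v, fs, highpass)
    v <- v - trend + mean(trend)   # remove drift, keep the absolute level
  }
  new_vm_trace(v, fs, trace$cell_id, trace$condition)
}

# Zero-phase slow-trend estimate: centred running mean over 1/highpass s,
# falling back to a linear fit when the window exceeds the trace.
slow_trend <- function(v, fs, highpass) {
  n <- length(v)
  w <- round(fs / highpass)
  if (w >= n) {
    t <- seq_len(n)
    unname(stats::fitted(lm(v ~ t)))
  } else {
    if (w %% 2 == 0) w <- w + 1
    k <- (w - 1) / 2
    cs <- cumsum(c(0, v))
    lo <- pmax(0, seq_len(n) - k - 1)
    hi <- pmin(n, seq_len(n) + k)
    (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  }
}

#' Detect and remove action potentials from a trace
#'
#' Action potential times are detected by thresholding (peaks of contiguous
#' supra-threshold runs). Each spike is excised by replacing the segment from
#' `pre_ms` before to `post_ms` after the peak with a straight line between
#' the boundary samples; overlapping segments are merged before interpolation.
#'
#' @param trace A `vm_trace`.
#' @param threshold Detection threshold (mV); must be above the trace median.
#' @param pre_ms Milliseconds removed before each peak.
#' @param post_ms Milliseconds removed after each peak (10-20 ms depending on
#'   spike shape).
#'
#' @return A list with `trace` (the despiked `vm_trace`) and `spike_times`
#'   (numeric vector, s).
#' @export
remove_spikes <- function(trace, threshold = -20, pre_ms = 2, post_ms = 10) {
  stopifnot(inherits(trace, "vm_trace"))
  if (post_ms < 10 || post_ms > 20) {
    stop("`post_ms` must lie in [10, 20]")
  }
  v <- trace$samples
  fs <- trace$sampling_rate
  if (threshold < median(v)) {
    stop("`threshold` is below the trace median; this would remove the whole trace")
  }
  above <- v > threshold
  if (!any(above)) {
    return(list(trace = trace, spike_times = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  peaks <- vapply(runs, function(j) {
    i <- starts[j]:ends[j]
    i[which.max(v[i])]
  }, integer(1))

  n <- length(v)
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  lo <- pmax(1L, peaks - pre)
  hi <- pmin(n, peaks + post)
  # merge overlapping excision spans
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  m_lo <- lo[1]; m_hi <- hi[1]
  merged <- list()
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= m_hi + 1L) {
      m_hi <- max(m_hi, hi[k])
    } else {
      merged[[length(merged) + 1]] <- c(m_lo, m_hi)
      m_lo <- lo[k]; m_hi <- hi[k]
    }
  }
  merged[[length(merged) + 1]] <- c(m_lo, m_hi)
  for (sp in merged) {
    a <- max(1L, sp[1] - 1L)
    b <- min(n, sp[2] + 1L)
    v[sp[1]:sp[2]] <- approx(c(a, b), v[c(a, b)], xout = sp[1]:sp[2])$y
  }
  list(trace = new_vm_trace(v, fs, trace$cell_id, trace$condition),
       spike_times = (peaks - 1) / fs)
}

# Indices of teleportation events of a given type that fit fully in the trace.
teleport_events <- function(trace, timeline, type, pre, post) {
  stopifnot(type %in% TELEPORT_TYPES)
  fs <- trace$sampling_rate
  n <- length(trace$samples)
  tt <- timeline$time_s[timeline$kind == "teleport" &
                          timeline$teleport_type %in% type]
  if (!length(tt)) {
    stop(sprintf("no teleportation events of type %s in the timeline", type))
  }
  i0 <- floor(tt * fs) + 1L
  ok <- (i0 - round(pre * fs)) >= 1 & (i0 + round(post * fs)) <= n
  if (any(!ok)) {
    warning(sprintf("%d %s event(s) extend past the trace and were skipped",
                    sum(!ok), type))
  }
  if (!any(ok)) {
    stop(sprintf("all %s events extend past the trace", type))
  }
  i0[ok]
}

#' Teleportation-aligned average of a membrane-potential trace
#'
#' Extracts a window around every teleportation of the requested type,
#' subtracts the per-event baseline (mean over the pre-window), and averages
#' across events. Optionally smooths the mean trace with a zero-phase low-pass
#' for display-grade averages.
#'
#' @param trace A `vm_trace`.
#' @param timeline A `session_timeline`.
#' @param type Teleportation type: one of `"FF"`, `"FN"`, `"NN"`, `"NF"`.
#' @param window Numeric `c(pre, post)` in seconds.
#' @param smooth_hz Optional zero-phase low-pass cutoff (Hz) applied to the
#'   mean trace (e.g. 10 Hz for display).
#'
#' @return An `aligned_average`: list with `time` (s, 0 = teleport),
#'   `mean_trace`, `sem_trace` (mV), `n_events`, `teleport_type`, `window`.
#' @export
teleportation_aligned_average <- function(trace, timeline, type,
                                          window = c(2, 3),
                                          smooth_hz = NULL) {
  fs <- trace$sampling_rate
  i0 <- teleport_events(trace, timeline, type, window[1], window[2])
  pre <- round(window[1] * fs)
  post <- round(window[2] * fs)
  rel <- (-pre):(post - 1L)
  seg <- vapply(i0, function(i) {
    w <- trace$samples[i + rel]
    w - mean(w[seq_len(pre)])
  }, numeric(length(rel)))
  seg <- matrix(seg, nrow = length(rel))
  m <- rowMeans(seg)
  s <- if (ncol(seg) > 1) apply(seg, 1, sd) / sqrt(ncol(seg)) else rep(NA_real_, nrow(seg))
  if (!is.null(smooth_hz)) {
    bf <- signal::butter(2, smooth_hz / (fs / 2), type = "low")
    m <- signal::filtfilt(bf, m)
  }
  structure(list(time = rel / fs, mean_trace = m, sem_trace = s,
                 n_events = length(i0), teleport_type = type,
                 window = window, sampling_rate = fs),
            class = "aligned_average")
}

#' @export
print.aligned_average <- function(x, ...) {
  post1 <- x$mean_trace[x$time > 0 & x$time <= 1]
  cat(sprintf("Teleportation-aligned average (%s): %d events, mean over (0,1] s = %.2f mV\n",
              x$teleport_type, x$n_events, mean(post1)))
  invisible(x)
}

#' @export
plot.aligned_average <- function(x, ...) {
  plot(x$time, x$mean_trace, type = "l", xlab = "time from teleportation (s)",
       ylab = expression(paste(Delta, "Vm (mV)")),
       main = paste(x$teleport_type, "aligned average"), ...)
  if (all(is.finite(x$sem_trace))) {
    polygon(c(x$time, rev(x$time)),
            c(x$mean_trace + x$sem_trace, rev(x$mean_trace - x$sem_trace)),
            border = NA, col = grDevices::adjustcolor("grey", 0.5))
    lines(x$time, x$mean_trace)
  }
  abline(v = 0, lty = 2, col = "red")
  invisible(x)
}

#' Teleportation-triggered change in membrane potential and variance
#'
#' For every teleportation of the requested type, computes the mean membrane
#' potential in the `post_window` seconds after the event minus the baseline
#' mean over the `pre_window` seconds before it (delta-Vm), and the analogous
#' difference of windowed variances. Events whose windows extend past the
#' trace are skipped with a warning.
#'
#' @param trace A `vm_trace` (preprocessed, spikes removed).
#' @param timeline A `session_timeline`.
#' @param type Teleportation type.
#' @param post_window Post-event averaging window (s); the 1-s convention.
#' @param pre_window Baseline window before the event (s).
#'
#' @return A `delta_vm` object: `delta_vm` (mV, mean over events),
#'   `delta_variance` (mV^2), `per_event` data frame, `n_events`, `teleport_type`.
#' @export
compute_delta_vm <- function(trace, timeline, type, post_window = 1,
                             pre_window = 1) {
  fs <- trace$sampling_rate
  i0 <- teleport_events(trace, timeline, type, pre_window, post_window)
  pre <- round(pre_window * fs)
  post <- round(post_window * fs)
  per <- t(vapply(i0, function(i) {
    b <- trace$samples[(i - pre):(i - 1L)]
    a <- trace$samples[i:(i + post - 1L)]
    c(dvm = mean(a) - mean(b), dvar = var(a) - var(b))
  }, numeric(2)))
  per_event <- data.frame(time_s = (i0 - 1) / fs, delta_vm = per[, "dvm"],
                          delta_variance = per[, "dvar"])
  structure(list(delta_vm = mean(per_event$delta_vm),
                 delta_variance = mean(per_event$delta_variance),
                 per_event = per_event, n_events = nrow(per_event),
                 teleport_type = type,
                 post_window = post_window, pre_window = pre_window),
            class = "delta_vm")
}

#' @export
print.delta_vm <- function(x, ...) {
  cat(sprintf("delta-Vm (%s, %d events): %.3f mV; delta-variance %.3f mV^2\n",
              x$teleport_type, x$n_events, x$delta_vm, x$delta_variance))
  invisible(x)
}

#' Behavioural hit rate (hits per lap)
#'
#' A lap scores a hit when it contains at least one lick in the anticipation
#' zone - the quarter of the corridor preceding reward-zone entry - before the
#' lap's reward (if any) is delivered.
#'
#' @param timeline A `session_timeline` containing lap markers (and lick
#'   events for a nonzero rate).
#' @return Hits per lap, in `[0, 1]`.
#' @export
#' @examples
#' b <- generate_behaviour_session(20, anticipation_prob = 1, seed = 1)
#' hit_rate(b)
hit_rate <- function(timeline) {
  stopifnot(inherits(timeline, "session_timeline"))
  if (!any(timeline$kind == "lap_start") || is.null(timeline$lap)) {
    stop("timeline has no lap markers")
  }
  zone <- reward_zone_geometry()$anticipation
  n_laps <- max(timeline$lap[timeline$kind == "lap_start"])
  hits <- 0L
  for (k in seq_len(n_laps)) {
    lk <- timeline[timeline$lap == k, , drop = FALSE]
    rew_t <- suppressWarnings(min(lk$time_s[lk$kind == "reward"]))
    licks <- lk[lk$kind == "lick" &
                  lk$position_cm >= zone[1] & lk$position_cm < zone[2] &
                  lk$time_s < rew_t, , drop = FALSE]
    if (nrow(licks)) hits <- hits + 1L
  }
  hits / n_laps
}

#' Nonparametric test with optional Bonferroni correction
#'
#' Thin wrapper over the field-standard tests: two-sided Wilcoxon signed-rank
#' for paired samples, two-sided Mann-Whitney U for unpaired samples, and the
#' Friedman test for multiple dependent samples. When `n_comparisons > 1` the
#' Bonferroni-corrected p-value `min(1, p * n_comparisons)` is reported.
#'
#' @param test_name One of `"wilcoxon_signed_rank"`, `"mann_whitney_u"`,
#'   `"friedman"`.
#' @param sample_a Numeric vector, or a matrix (subjects x conditions) for the
#'   Friedman test.
#' @param sample_b Second sample (ignored for Friedman).
#' @param n_comparisons Number of comparisons for the Bonferroni correction.
#'
#' @return A `stat_report`: `test_name`, `statistic`, `p_value`,
#'   `corrected_p` (or `NA` when no correction applies), `n`.
#' @export
#' @examples
#' run_stat("mann_whitney_u", rnorm(20), rnorm(20, 2))
run_stat <- function(test_name = c("wilcoxon_signed_rank", "mann_whitney_u",
                                   "friedman"),
                     sample_a, sample_b = NULL, n_comparisons = 1) {
  test_name <- match.arg(test_name)
  if (test_name == "friedman") {
    ht <- friedman.test(as.matrix(sample_a))
    n <- nrow(as.matrix(sample_a))
  } else if (test_name == "wilcoxon_signed_rank") {
    if (length(sample_a) != length(sample_b)) {
      stop("paired samples must have equal length")
    }
    if (all(sample_a == sample_b)) {
      stop("signed-rank test undefined: all paired differences are zero")
    }
    ht <- suppressWarnings(wilcox.test(sample_a, sample_b, paired = TRUE))
    n <- length(sample_a)
  } else {
    ht <- suppressWarnings(wilcox.test(sample_a, sample_b, paired = FALSE))
    n <- length(sample_a) + length(sample_b)
  }
  corrected <- if (n_comparisons > 1) min(1, ht$p.value * n_comparisons) else NA_real_
  structure(list(test_name = test_name,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, corrected_p = corrected, n = n),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3g, p = %.3g%s (n = %d)\n",
              x$test_name, x$statistic, x$p_value,
              if (!is.na(x$corrected_p))
                sprintf(", Bonferroni-corrected p = %.3g", x$corrected_p)
              else "", x$n))
  invisible(x)
}

#' Per-cell delta-Vm over a recording set
#'
#' Convenience pipeline: preprocess (slow-trend removal), remove spikes, and
#' compute per-cell delta-Vm for one teleportation type across a list of
#' synthetic (or loaded) recordings.
#'
#' @param recordings List of `list(timeline=, trace=)` pairs, e.g. from
#'   [generate_recording_set()].
#' @param type Teleportation type.
#' @param lowpass,highpass Preprocessing settings (see [preprocess_trace()]).
#' @param spike_threshold Spike-removal threshold (mV).
#' @return Data frame with one row per cell: `cell_id`, `delta_vm`,
#'   `delta_variance`, `n_events`.
#' @export
delta_vm_by_cell <- function(recordings, type, lowpass = NULL,
                             highpass = 1e-5, spike_threshold = -20) {
  rows <- lapply(recordings, function(r) {
    tr <- preprocess_trace(r$trace, lowpass = lowpass, highpass = highpass)
    tr <- remove_spikes(tr, threshold = spike_threshold)$trace
    d <- compute_delta_vm(tr, r$timeline, type)
    data.frame(cell_id = r$trace$cell_id, delta_vm = d$delta_vm,
               delta_variance = d$delta_variance, n_events = d$n_events)
  })
  do.call(rbind, rows)
}
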