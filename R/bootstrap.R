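# Bootstrap estimator of the population spiking effect of the novelty
# transient: shift silent-cell traces over a distribution of baselines, add
# the depolarisation waveform at every sampling point, and count
# action-potential threshold crossings in the following second.

#' Configuration for the spiking-fraction bootstrap
#'
#' @param n_baselines Number of baseline membrane potentials drawn per trace
#'   (>= 1).
#' @param baseline_mean,baseline_sd,baseline_skew Parameters of the skewed
#'   baseline distribution (mV; see [sample_baseline_vm()]).
#' @param threshold_mean,threshold_sd Gaussian action-potential threshold
#'   model (mV), drawn once per trace. The true threshold distribution is not
#'   published; these defaults are a documented synthetic stand-in.
#' @param window Look-ahead window for threshold crossings (s).
#' @param stride Spacing between evaluated sampling points (s). Every point is
#'   evaluated when `stride` equals one sample.
#' @param seed Integer seed.
#'
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_baselines = 1000, baseline_mean = -73,
                             baseline_sd = 9, baseline_skew = 4,
                             threshold_mean = -45, threshold_sd = 3,
                             window = 1, stride = 0.01, seed = 1) {
  if (n_baselines < 1) stop("`n_baselines` must be >= 1")
  if (threshold_mean <= baseline_mean) {
    stop("threshold model must lie above the baseline mean")
  }
  structure(list(n_baselines = n_baselines, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, baseline_skew = baseline_skew,
                 threshold_mean = threshold_mean, threshold_sd = threshold_sd,
                 window = window, stride = stride, seed = seed),
            class = "bootstrap_config")
}

#' Shift a trace so its baseline matches a target
#'
#' The baseline is the mean membrane potential during the first second of the
#' recording; the whole trace is offset additively so this baseline equals
#' `target_baseline`, preserving the waveform exactly.
#'
#' @param trace A `vm_trace` of at least 1 s.
#' @param target_baseline Target baseline (mV).
#' @return A shifted `vm_trace`.
#' @export
shift_trace_to_baseline <- function(trace, target_baseline) {
  stopifnot(inherits(trace, "vm_trace"))
  n1 <- round(trace$sampling_rate)
  if (length(trace$samples) < n1) {
    stop("trace must be at least 1 s long to define a baseline")
  }
  b <- mean(trace$samples[seq_len(n1)])
  new_vm_trace(trace$samples + (target_baseline - b), trace$sampling_rate,
               trace$cell_id, trace$condition)
}

#' Bootstrap the fraction of granule cells recruited to spike
#'
#' For every trace, every drawn baseline, and every sampling point (on a
#' stride), the trace is shifted so its first-second mean equals the baseline,
#' the depolarisation waveform is added starting at the sampling point, and a
#' spike is scored if any sample in the following `window` seconds exceeds the
#' trace's action-potential threshold. The spiking fractions with and without
#' the waveform are the averages of these indicators; their ratio minus one is
#' the relative increase in the spiking population caused by the novelty
#' signal.
#'
#' @param traces List of spike-free `vm_trace` objects from silent cells.
#' @param waveform Numeric depolarisation waveform (mV), at the traces'
#'   sampling rate, covering at least `window` seconds (e.g. from
#'   [novelty_waveform()]).
#' @param config A [bootstrap_config()].
#'
#' @return A `spiking_bootstrap` object: `frac_spiking_with`,
#'   `frac_spiking_without`, `relative_increase`, `per_trace` data frame, and
#'   the evaluation counts.
#' @export
#' @examples
#' tl <- generate_session_timeline(2, lap_duration_stats = c(4, 0), seed = 1)
#' spec <- vm_generator_spec(spike_rate = 0, seed = 1)
#' tr <- generate_vm_trace(spec, tl, inject_novelty_on = character(0))
#' w <- novelty_waveform(1.02, 0.8, 1000)
#' bootstrap_spiking_fraction(list(tr), w, bootstrap_config(n_baselines = 50))
bootstrap_spiking_fraction <- function(traces, waveform,
                                       config = bootstrap_config()) {
  if (!length(traces)) stop("`traces` must contain at least one trace")
  stopifnot(all(vapply(traces, inherits, logical(1), "vm_trace")))
  fs <- traces[[1]]$sampling_rate
  win <- round(config$window * fs)
  if (length(waveform) < win) {
    stop("`waveform` must cover at least the look-ahead window")
  }
  set.seed(config$seed)
  baselines <- sample_baseline_vm(config$n_baselines, config$baseline_mean,
                                  config$baseline_sd, config$baseline_skew)
  thresholds <- rnorm(length(traces), config$threshold_mean,
                      config$threshold_sd)
  stride <- max(1L, round(config$stride * fs))
  w <- waveform[seq_len(win)]

  per <- lapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    if (tr$sampling_rate != fs) stop("all traces must share one sampling rate")
    v <- tr$samples
    n1 <- round(fs)
    if (length(v) < n1 + win) stop("trace too short for the look-ahead window")
    v0 <- v - mean(v[seq_len(n1)])              # baseline-zeroed waveform
    pts <- seq(1L, length(v0) - win + 1L, by = stride)
    # window maxima without and with the added waveform
    m0 <- vapply(pts, function(i) max(v0[i:(i + win - 1L)]), numeric(1))
    m1 <- vapply(pts, function(i) max(v0[i:(i + win - 1L)] + w), numeric(1))
    # crossing indicators over all (baseline, point) pairs
    th <- thresholds[k]
    c0 <- outer(baselines, m0, function(b, m) b + m > th)
    c1 <- outer(baselines, m1, function(b, m) b + m > th)
    data.frame(cell_id = tr$cell_id, n_points = length(pts),
               frac_without = mean(c0), frac_with = mean(c1),
               threshold = th)
  })
  per <- do.call(rbind, per)
  f0 <- mean(per$frac_without)
  f1 <- mean(per$frac_with)
  rel <- if (f1 == f0) 0 else if (f0 > 0) f1 / f0 - 1 else NA_real_
  structure(list(frac_spiking_with = f1, frac_spiking_without = f0,
                 relative_increase = rel, per_trace = per,
                 n_baselines = config$n_baselines,
                 n_traces = length(traces)),
            class = "spiking_bootstrap")
}

#' @export
print.spiking_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Spiking-fraction bootstrap (%d traces x %d baselines)\n", x$n_traces,
    x$n_baselines))
  cat(sprintf("  fraction spiking: %.4f without vs %.4f with the novelty signal\n",
              x$frac_spiking_without, x$frac_spiking_with))
  if (is.finite(x$relative_increase)) {
    cat(sprintf("  relative increase: %.1f%%\n", 100 * x$relative_increase))
  }
  invisible(x)
}
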