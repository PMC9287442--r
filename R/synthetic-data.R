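# Synthetic granule-cell recordings: skewed baseline distribution, OU-type
# subthreshold fluctuations, teleportation-locked depolarising transients,
# stereotyped spikes, and virtual-corridor session timelines.

#' Generator settings for synthetic granule-cell membrane potential
#'
#' Bundles the parameters of the synthetic membrane-potential generator.
#' Defaults reproduce the in-vivo statistics of dentate gyrus granule cells:
#' a right-skewed baseline distribution (-73 +/- 9 mV, skew-normal shape 4),
#' mean-reverting subthreshold noise, and a ~1 mV teleportation-locked
#' depolarising transient whose mean over the first second equals
#' `novelty_amplitude` and which has decayed to a few percent of its peak
#' by 2-3 s.
#'
#' @param baseline_mean Mean of the baseline membrane-potential distribution (mV).
#' @param baseline_sd Standard deviation of the baseline distribution (mV); must be > 0.
#' @param baseline_skew Shape parameter of the skew-normal baseline distribution
#'   (0 gives a plain Gaussian).
#' @param noise_sd Stationary s.d. of the mean-reverting (Ornstein-Uhlenbeck)
#'   subthreshold noise (mV).
#' @param noise_timescale Correlation time of the subthreshold noise (s).
#' @param novelty_amplitude Mean of the injected transient over the first
#'   second after a teleportation (mV).
#' @param novelty_decay Exponential decay constant of the transient (s); must be > 0.
#' @param spike_threshold Membrane potential at which synthetic action
#'   potentials initiate (mV).
#' @param spike_rate Poisson rate of synthetic action potentials (Hz).
#' @param sampling_rate Sampling rate of the generated trace (Hz); must be > 0.
#' @param seed Optional integer seed making the generator reproducible.
#'
#' @return An object of class `vm_generator_spec`.
#' @seealso [generate_vm_trace()], [novelty_waveform()]
#' @export
#' @examples
#' spec <- vm_generator_spec()
#' spec
vm_generator_spec <- function(baseline_mean = -73, baseline_sd = 9,
                              baseline_skew = 4, noise_sd = 2,
                              noise_timescale = 0.05,
                              novelty_amplitude = 1.02, novelty_decay = 0.8,
                              spike_threshold = -45, spike_rate = 0.02,
                              sampling_rate = 1000, seed = NULL) {
  if (baseline_sd <= 0) stop("`baseline_sd` must be > 0")
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0")
  if (novelty_decay <= 0) stop("`novelty_decay` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (spike_rate < 0) stop("`spike_rate` must be >= 0")
  spec <- list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               baseline_skew = baseline_skew, noise_sd = noise_sd,
               noise_timescale = noise_timescale,
               novelty_amplitude = novelty_amplitude,
               novelty_decay = novelty_decay,
               spike_threshold = spike_threshold, spike_rate = spike_rate,
               sampling_rate = sampling_rate, seed = seed)
  class(spec) <- "vm_generator_spec"
  spec
}

#' @export
print.vm_generator_spec <- function(x, ...) {
  cat("Membrane-potential generator spec\n")
  cat(sprintf("  baseline: %.1f +/- %.1f mV (skew shape %.1f)\n",
              x$baseline_mean, x$baseline_sd, x$baseline_skew))
  cat(sprintf("  noise: OU sd %.1f mV, tau %.0f ms\n",
              x$noise_sd, 1000 * x$noise_timescale))
  cat(sprintf("  novelty transient: %.2f mV (1-s mean), decay %.2f s\n",
              x$novelty_amplitude, x$novelty_decay))
  cat(sprintf("  spikes: %.3g Hz above %.0f mV; sampling %.0f Hz\n",
              x$spike_rate, x$spike_threshold, x$sampling_rate))
  invisible(x)
}

#' Draw baseline membrane potentials from a skew-normal distribution
#'
#' Samples `n` baseline membrane potentials from a skew-normal distribution
#' whose population mean and standard deviation equal the requested values.
#' `skew` is the skew-normal shape parameter; the location and scale are
#' corrected analytically so that the first two moments are exact. With
#' `skew = 0` this is an ordinary Gaussian.
#'
#' @param n Number of draws (>= 1).
#' @param mean Target population mean (mV).
#' @param sd Target population s.d. (mV); must be > 0.
#' @param skew Skew-normal shape parameter.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of `n` membrane potentials (mV).
#' @export
#' @examples
#' v <- sample_baseline_vm(1000, seed = 1)
#' mean(v); sd(v)
sample_baseline_vm <- function(n, mean = -73, sd = 9, skew = 4, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  if (sd <= 0) stop("`sd` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  delta <- skew / sqrt(1 + skew^2)
  z0 <- rnorm(n)
  z1 <- rnorm(n)
  z <- delta * abs(z0) + sqrt(1 - delta^2) * z1   # skew-normal(shape) variate
  mz <- delta * sqrt(2 / pi)
  sz <- sqrt(1 - 2 * delta^2 / pi)
  mean + sd * (z - mz) / sz
}

#' Teleportation-locked depolarising transient waveform
#'
#' Single-exponential depolarising waveform whose *discrete* mean over the
#' first `window` seconds equals `amplitude`, matching the convention used to
#' report the transient as a 1-s mean depolarisation.
#'
#' @param amplitude Mean of the waveform over the first `window` seconds (mV).
#' @param decay Exponential decay constant (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param duration Total waveform duration (s); default runs the tail out to
#'   five decay constants.
#' @param window Averaging window defining the amplitude (s).
#'
#' @return Numeric vector of waveform samples (mV).
#' @export
novelty_waveform <- function(amplitude, decay, sampling_rate,
                             duration = 5 * decay, window = 1) {
  nw <- max(1L, round(window * sampling_rate))
  nt <- max(nw, round(duration * sampling_rate))
  t <- (seq_len(nt) - 1) / sampling_rate
  shape <- exp(-t / decay)
  peak <- amplitude / mean(shape[seq_len(nw)])
  peak * shape
}

# -- session timelines --------------------------------------------------------

TELEPORT_TYPES <- c("FF", "FN", "NN", "NF")
TRACK_LENGTH_CM <- 120

new_session_timeline <- function(events, env_sequence, lap_starts, duration) {
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(events,
            env_sequence = env_sequence,
            lap_starts = lap_starts,
            duration = duration,
            track_length = TRACK_LENGTH_CM,
            class = c("session_timeline", "data.frame"))
}

#' Generate a lap/teleportation session timeline
#'
#' Builds the event timeline of a virtual-corridor session: one lap per entry
#' of `env_sequence` ("F" familiar, "N" novel), with a teleportation event at
#' every lap boundary whose type (FF/FN/NN/NF) is the (from, to) environment
#' pair. Teleportations reset position to 0 on a 120-cm track.
#'
#' @param n_laps Number of laps (>= 1).
#' @param env_sequence Character vector of `"F"`/`"N"` labels, one per lap.
#'   Defaults to repeating F,F,N,N blocks so all four teleportation types occur.
#' @param lap_duration_stats Numeric length-2 vector `c(mean, sd)` of lap
#'   durations in seconds.
#' @param seed Optional integer seed.
#'
#' @return A `session_timeline`: a data frame of events (`time_s`, `kind`,
#'   `teleport_type`, `position_cm`, `lap`) with session attributes.
#' @export
#' @examples
#' tl <- generate_session_timeline(8, seed = 1)
#' table(tl$teleport_type[tl$kind == "teleport"])
generate_session_timeline <- function(n_laps,
                                      env_sequence = NULL,
                                      lap_duration_stats = c(9, 1),
                                      seed = NULL) {
  if (n_laps < 1) stop("`n_laps` must be >= 1")
  if (is.null(env_sequence)) {
    env_sequence <- rep(c("F", "F", "N", "N"), length.out = n_laps)
  }
  if (length(env_sequence) != n_laps) {
    stop("`env_sequence` must have length `n_laps`")
  }
  bad <- which(!env_sequence %in% c("F", "N"))
  if (length(bad)) {
    stop(sprintf("invalid environment label %s at index %d",
                 dQuote(env_sequence[bad[1]]), bad[1]))
  }
  if (!is.null(seed)) set.seed(seed)
  durs <- pmax(1, rnorm(n_laps, lap_duration_stats[1], lap_duration_stats[2]))
  lap_starts <- c(0, cumsum(durs)[-n_laps])
  duration <- sum(durs)

  starts <- data.frame(time_s = lap_starts, kind = "lap_start",
                       teleport_type = NA_character_, position_cm = 0,
                       lap = seq_len(n_laps))
  events <- starts
  if (n_laps > 1) {
    ttype <- paste0(env_sequence[-n_laps], env_sequence[-1])
    tel <- data.frame(time_s = lap_starts[-1], kind = "teleport",
                      teleport_type = ttype, position_cm = 0,
                      lap = seq_len(n_laps)[-1])
    events <- rbind(events, tel)
  }
  new_session_timeline(events, env_sequence, lap_starts, duration)
}

#' @export
print.session_timeline <- function(x, ...) {
  tel <- x$teleport_type[x$kind == "teleport"]
  cat(sprintf("Session timeline: %d laps, %.1f s, %d events\n",
              length(attr(x, "env_sequence")), attr(x, "duration"), nrow(x)))
  if (length(tel)) {
    cat("  teleportations:",
        paste(sprintf("%s=%d", names(table(tel)), table(tel)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.session_timeline <- function(object, ...) {
  list(n_laps = length(attr(object, "env_sequence")),
       duration_s = attr(object, "duration"),
       events = table(object$kind),
       teleport_types = table(object$teleport_type[object$kind == "teleport"]))
}

#' Write / read a session timeline as CSV
#'
#' Plain-text interchange format: columns `time_s`, `kind`, `teleport_type`,
#' `position_cm`, `lap`, UTF-8, header row, `.` decimal separator.
#'
#' @param timeline A `session_timeline`.
#' @param path File path.
#' @return `write_session_timeline` returns `path` invisibly;
#'   `read_session_timeline` returns a `session_timeline`.
#' @export
write_session_timeline <- function(timeline, path) {
  utils::write.csv(as.data.frame(timeline), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_timeline
#' @export
read_session_timeline <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  laps <- ev$time_s[ev$kind == "lap_start"]
  env <- rep("F", length(laps))  # environment labels are not stored in CSV
  new_session_timeline(ev, env, laps, max(ev$time_s))
}

# -- membrane potential traces ------------------------------------------------

new_vm_trace <- function(samples, sampling_rate, cell_id = "cell",
                         condition = "control") {
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 cell_id = cell_id, condition = condition),
            class = "vm_trace")
}

#' Construct a membrane-potential trace object
#'
#' @param samples Numeric vector of membrane potential samples (mV); must be finite.
#' @param sampling_rate Sampling rate (Hz).
#' @param cell_id Cell identifier.
#' @param condition `"control"` or `"atropine"`.
#' @return A `vm_trace` object.
#' @export
vm_trace <- function(samples, sampling_rate, cell_id = "cell",
                     condition = c("control", "atropine")) {
  condition <- match.arg(condition)
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0")
  new_vm_trace(as.numeric(samples), sampling_rate, cell_id, condition)
}

#' @export
print.vm_trace <- function(x, ...) {
  cat(sprintf("Vm trace '%s' (%s): %.1f s at %g Hz, mean %.1f mV\n",
              x$cell_id, x$condition, length(x$samples) / x$sampling_rate,
              x$sampling_rate, mean(x$samples)))
  invisible(x)
}

#' @export
plot.vm_trace <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$sampling_rate
  plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "Vm (mV)",
       main = x$cell_id, ...)
  invisible(x)
}

ou_noise <- function(n, sd, tau, sampling_rate) {
  if (sd == 0 || n == 0) return(numeric(n))
  rho <- exp(-1 / (sampling_rate * tau))
  innov <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  innov[1] <- rnorm(1, 0, sd)  # start in the stationary distribution
  as.numeric(filter(innov, rho, method = "recursive"))
}

#' Generate a synthetic membrane-potential trace for a session
#'
#' Produces baseline + mean-reverting Gaussian noise, adds a deterministic
#' exponential-decay depolarising transient at every teleportation whose type
#' is in `inject_novelty_on`, and optionally superimposes brief stereotyped
#' spikes at Poisson times. The transient is additive, so it changes the mean
#' but not the variance of the trace.
#'
#' @param spec A [vm_generator_spec()].
#' @param timeline A `session_timeline`; the trace covers its full duration.
#' @param inject_novelty_on Character vector of teleportation types
#'   (subset of FF, FN, NN, NF) that receive the transient. Empty vector
#'   injects nothing.
#' @param cell_id Cell identifier stored in the trace.
#' @param condition Recording condition label.
#' @param seed Optional integer seed (defaults to `spec$seed`).
#'
#' @return A `vm_trace`.
#' @export
#' @examples
#' tl <- generate_session_timeline(4, seed = 1)
#' tr <- generate_vm_trace(vm_generator_spec(seed = 1), tl)
#' tr
generate_vm_trace <- function(spec, timeline, inject_novelty_on = "FN",
                              cell_id = "cell", condition = "control",
                              seed = spec$seed) {
  stopifnot(inherits(spec, "vm_generator_spec"),
            inherits(timeline, "session_timeline"))
  if (nrow(timeline) == 0) stop("`timeline` is empty")
  unknown <- setdiff(inject_novelty_on, TELEPORT_TYPES)
  if (length(unknown)) {
    stop("unknown teleportation type(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- spec$sampling_rate
  n <- ceiling(attr(timeline, "duration") * fs)

  baseline <- sample_baseline_vm(1, spec$baseline_mean, spec$baseline_sd,
                                 spec$baseline_skew)
  v <- baseline + ou_noise(n, spec$noise_sd, spec$noise_timescale, fs)

  tel <- timeline[timeline$kind == "teleport" &
                    timeline$teleport_type %in% inject_novelty_on, ]
  if (nrow(tel)) {
    w <- novelty_waveform(spec$novelty_amplitude, spec$novelty_decay, fs)
    for (tt in tel$time_s) {
      i0 <- floor(tt * fs) + 1L
      idx <- i0:min(n, i0 + length(w) - 1L)
      if (length(idx)) v[idx] <- v[idx] + w[seq_along(idx)]
    }
  }

  if (spec$spike_rate > 0) {
    n_sp <- rpois(1, spec$spike_rate * n / fs)
    if (n_sp > 0) {
      sp_t <- sort(runif(n_sp, 0, n / fs))
      half <- max(1L, round(0.001 * fs))            # 2-ms triangular spike
      shape <- c(seq_len(half), rev(seq_len(half))) / half
      for (tt in sp_t) {
        i0 <- floor(tt * fs) + 1L
        idx <- i0:min(n, i0 + length(shape) - 1L)
        v[idx] <- pmax(v[idx], spec$spike_threshold + 80 * shape[seq_along(idx)])
      }
    }
  }
  new_vm_trace(v, fs, cell_id, condition)
}

#' Generate a multi-cell synthetic recording set
#'
#' One master seed spawns an independent child stream per cell, giving a
#' reproducible dataset of (timeline, trace) pairs with identical session
#' structure statistics.
#'
#' @param n_cells Number of cells.
#' @param spec A [vm_generator_spec()].
#' @param n_laps Laps per session.
#' @param env_sequence Per-lap environment labels (recycled default as in
#'   [generate_session_timeline()]).
#' @param inject_novelty_on Teleportation types receiving the transient.
#' @param seed Master seed.
#'
#' @return List of `n_cells` elements, each `list(timeline=, trace=)`.
#' @export
generate_recording_set <- function(n_cells, spec = vm_generator_spec(),
                                   n_laps = 12, env_sequence = NULL,
                                   inject_novelty_on = "FN", seed = 1) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, 2 * n_cells)
  lapply(seq_len(n_cells), function(k) {
    tl <- generate_session_timeline(n_laps, env_sequence, seed = child[2 * k - 1])
    tr <- generate_vm_trace(spec, tl, inject_novelty_on,
                            cell_id = sprintf("cell%02d", k),
                            seed = child[2 * k])
    list(timeline = tl, trace = tr)
  })
}

# -- behaviour ----------------------------------------------------------------

#' Generate a behavioural session with licks and rewards
#'
#' Emulates the un-cued reward-zone task: trained sessions produce anticipatory
#' licks in the quarter of the corridor preceding reward-zone entry with
#' probability `anticipation_prob` per lap (followed by a reward, standing for
#' the stop-duration rule being met); untrained sessions produce licks at
#' positions uncorrelated with the track.
#'
#' @param n_laps Number of laps (>= 1).
#' @param trained Logical; trained animals lick in anticipation of reward.
#' @param anticipation_prob Per-lap probability of an anticipatory lick.
#'   Defaults to 0.5 when `trained`, 0 otherwise.
#' @param lick_rate Poisson rate of position-uncorrelated licks per lap.
#' @param lap_duration_stats `c(mean, sd)` lap duration (s).
#' @param seed Optional integer seed.
#'
#' @return A `session_timeline` including `lick` and `reward` events.
#' @seealso [hit_rate()]
#' @export
generate_behaviour_session <- function(n_laps, trained = TRUE,
                                       anticipation_prob = NULL,
                                       lick_rate = if (trained) 0 else 2,
                                       lap_duration_stats = c(9, 1),
                                       seed = NULL) {
  if (n_laps < 1) stop("`n_laps` must be >= 1")
  if (is.null(anticipation_prob)) anticipation_prob <- if (trained) 0.5 else 0
  if (!is.null(seed)) set.seed(seed)
  tl <- generate_session_timeline(n_laps, rep("F", n_laps), lap_duration_stats)
  lap_starts <- attr(tl, "lap_starts")
  durs <- diff(c(lap_starts, attr(tl, "duration")))
  zone <- reward_zone_geometry()

  extra <- list()
  for (k in seq_len(n_laps)) {
    t0 <- lap_starts[k]; d <- durs[k]
    pos_to_t <- function(p) t0 + d * p / TRACK_LENGTH_CM
    if (runif(1) < anticipation_prob) {
      p_lick <- runif(1, zone$anticipation[1], zone$anticipation[2])
      extra[[length(extra) + 1]] <- data.frame(
        time_s = pos_to_t(p_lick), kind = "lick",
        teleport_type = NA_character_, position_cm = p_lick, lap = k)
      extra[[length(extra) + 1]] <- data.frame(
        time_s = pos_to_t(zone$reward[1] + 2), kind = "reward",
        teleport_type = NA_character_, position_cm = zone$reward[1] + 2, lap = k)
    }
    n_rand <- rpois(1, lick_rate)
    if (n_rand > 0) {
      p_r <- runif(n_rand, 0, TRACK_LENGTH_CM)
      extra[[length(extra) + 1]] <- data.frame(
        time_s = pos_to_t(p_r), kind = "lick",
        teleport_type = NA_character_, position_cm = p_r, lap = k)
    }
  }
  ev <- as.data.frame(tl)
  if (length(extra)) ev <- rbind(ev, do.call(rbind, extra))
  new_session_timeline(ev, attr(tl, "env_sequence"), lap_starts,
                       attr(tl, "duration"))
}

# Reward zone in the third quarter of the 120-cm corridor; the anticipation
# zone is the quarter of the track preceding reward-zone entry.
reward_zone_geometry <- function() {
  list(reward = c(60, 90), anticipation = c(30, 60))
}
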