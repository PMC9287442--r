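# Shared fixtures: small configurations and independent oracle helpers.

# Small network config for construction-level oracle tests.
toy_ca3_config <- function(...) {
  args <- list(n = 50, p = 5, pattern_size = 6, pf_diameter = 3,
               place_fraction = 0.8, inputs_per_unit = 20,
               S_min = 2, n_interneurons = 10, interneuron_fanout = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(ca3_config, args)
}

# Independent skew-normal sampler: rejection from the density 2*phi(z)*Phi(a z),
# deliberately avoiding the delta-representation used by the package.
rsn_reject <- function(n, shape) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- rnorm(2 * n)
    keep <- runif(length(z)) < pnorm(shape * z)
    out <- c(out, z[keep])
  }
  out[seq_len(n)]
}

# Moment-correct a standard skew-normal variate to target mean/sd.
sn_moment_correct <- function(z, mean, sd, shape) {
  delta <- shape / sqrt(1 + shape^2)
  mz <- delta * sqrt(2 / pi)
  sz <- sqrt(1 - 2 * delta^2 / pi)
  mean + sd * (z - mz) / sz
}

# Naive triple-loop bootstrap oracle (trace x baseline x sampling point).
naive_bootstrap <- function(traces, waveform, config) {
  fs <- traces[[1]]$sampling_rate
  win <- round(config$window * fs)
  set.seed(config$seed)
  baselines <- sample_baseline_vm(config$n_baselines, config$baseline_mean,
                                  config$baseline_sd, config$baseline_skew)
  thresholds <- rnorm(length(traces), config$threshold_mean,
                      config$threshold_sd)
  stride <- max(1L, round(config$stride * fs))
  w <- waveform[seq_len(win)]
  hits0 <- 0L; hits1 <- 0L; total <- 0L
  for (k in seq_along(traces)) {
    v <- traces[[k]]$samples
    v0 <- v - mean(v[seq_len(round(fs))])
    th <- thresholds[k]
    pts <- seq(1L, length(v0) - win + 1L, by = stride)
    for (b in baselines) {
      for (i in pts) {
        seg <- v0[i:(i + win - 1L)] + b
        hits0 <- hits0 + any(seg > th)
        hits1 <- hits1 + any(seg + w > th)
        total <- total + 1L
      }
    }
  }
  f0 <- hits0 / total; f1 <- hits1 / total
  list(frac_without = f0, frac_with = f1,
       relative_increase = if (f1 == f0) 0 else
         if (f0 > 0) f1 / f0 - 1 else NA_real_)
}

# Literal step-by-step transcription of the bounded BCM/Hebbian update,
# with explicit history vectors instead of ring buffers.
bcm_transcription_oracle <- function(J0, C, s_seq, h_seq, eta = 0.1,
                                     tau_l = 4, tau_b = 8, cc = 9.5,
                                     G = 2.31, Tn = 0.1,
                                     apply_at = function(t) t %% 2 == 0) {
  n <- ncol(C)
  Lfun <- function(h) atan((h - G) / Tn) / pi + 0.5
  J <- J0
  hist_s <- matrix(0, 0, n)
  hist_h2 <- matrix(0, 0, n)
  for (t in seq_len(nrow(s_seq))) {
    hb <- Lfun(h_seq[t, ])
    hist_h2 <- rbind(hist_h2, hb^2)
    if (apply_at(t) && t > tau_l) {
      lo <- max(1, nrow(hist_h2) - tau_b)
      phi <- cc / tau_b * colSums(hist_h2[lo:nrow(hist_h2), , drop = FALSE])
      sig_post <- ifelse(phi < 1e-12, 0, hb / phi * (hb - phi))
      lo_s <- max(1, nrow(hist_s) - tau_l + 1)
      mean_s <- if (nrow(hist_s))
        colSums(hist_s[lo_s:nrow(hist_s), , drop = FALSE]) / tau_l else 0
      sig_pre <- s_seq[t, ] - mean_s
      J[] <- pmin(1, pmax(0, J + eta * C * outer(sig_post, sig_pre)))
    }
    hist_s <- rbind(hist_s, s_seq[t, ])
  }
  J
}

# Quiet trace of a silent cell (no spikes, no transient).
silent_trace <- function(duration_s = 4, fs = 200, noise_sd = 2, seed = 1,
                         baseline = -73) {
  set.seed(seed)
  tl <- generate_session_timeline(2, c("F", "F"),
                                  lap_duration_stats = c(duration_s / 2, 0))
  spec <- vm_generator_spec(noise_sd = noise_sd, spike_rate = 0,
                            sampling_rate = fs)
  tr <- generate_vm_trace(spec, tl, inject_novelty_on = character(0),
                          seed = seed)
  tr$samples <- tr$samples - mean(tr$samples[seq_len(fs)]) + baseline
  tr
}
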