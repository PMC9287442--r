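# Preprocessing, spike removal, teleportation-aligned analysis, and
# nonparametric statistics.

test_that("filters pass constants and attenuate out-of-band components", {
  fs <- 50000
  const <- vm_trace(rep(-70, fs / 5), fs)
  out <- preprocess_trace(const, lowpass = 5000)
  core <- out$samples[2000:(length(out$samples) - 2000)]
  expect_lt(max(abs(core + 70)), 0.01)

  # 20 kHz sinusoid through a 5 kHz low-pass: > 20 dB attenuation
  t <- seq_len(fs / 5) / fs
  sine <- vm_trace(sin(2 * pi * 20000 * t), fs)
  outs <- preprocess_trace(sine, lowpass = 5000)
  core <- outs$samples[2000:(length(outs$samples) - 2000)]
  expect_lt(sqrt(mean(core^2)) / sqrt(0.5), 10^(-20 / 20))

  expect_error(preprocess_trace(const, lowpass = fs), "Nyquist")
})

test_that("slow-trend removal reduces a linear drift at least tenfold", {
  fs <- 100
  n <- 10 * 60 * fs                      # 10-minute trace
  drift <- (seq_len(n) / fs) * (1 / 60)  # 1 mV per minute
  set.seed(1)
  tr <- vm_trace(-70 + drift + rnorm(n, 0, 0.5), fs)
  out <- preprocess_trace(tr, highpass = 1e-5)
  t <- seq_len(n) / fs
  slope_in <- coef(lm(tr$samples ~ t))[2]
  slope_out <- coef(lm(out$samples ~ t))[2]
  expect_lt(abs(slope_out), abs(slope_in) / 10)
})

test_that("resampling preserves the waveform on the new grid", {
  fs <- 1000
  t <- (seq_len(fs) - 1) / fs
  tr <- vm_trace(-70 + sin(2 * pi * 5 * t), fs)
  out <- preprocess_trace(tr, resample_to = 250)
  expect_equal(out$sampling_rate, 250)
  t2 <- (seq_along(out$samples) - 1) / 250
  expect_lt(max(abs(out$samples - (-70 + sin(2 * pi * 5 * t2)))), 0.01)
})

test_that("spike removal detects, excises, and merges overlapping spans", {
  fs <- 1000
  v <- rep(-70, 2 * fs)
  tr0 <- vm_trace(v, fs)
  r0 <- remove_spikes(tr0, threshold = -20)
  expect_identical(r0$trace$samples, v)
  expect_length(r0$spike_times, 0)

  # single triangular spike at a known time
  peak_i <- 500
  v1 <- v
  v1[(peak_i - 2):(peak_i + 2)] <- c(-40, 0, 20, 0, -40)
  r1 <- remove_spikes(vm_trace(v1, fs), threshold = -20)
  expect_lt(abs(r1$spike_times - (peak_i - 1) / fs), 1.5 / fs)
  expect_true(all(r1$trace$samples <= -20))
  span <- (peak_i - 2):(peak_i + 10)     # pre 2 ms + post 10 ms
  expect_lt(max(abs(r1$trace$samples[span] + 70)), 1e-9)

  # two spikes 5 ms apart merge into one interpolated segment
  v2 <- v
  v2[500] <- 20; v2[505] <- 20
  r2 <- remove_spikes(vm_trace(v2, fs), threshold = -20)
  expect_length(r2$spike_times, 2)
  seg <- r2$trace$samples[495:518]
  expect_lt(max(abs(diff(diff(seg)))), 1e-9)  # one straight line across the union

  expect_error(remove_spikes(vm_trace(v, fs), threshold = -80), "median")
  expect_error(remove_spikes(tr0, post_ms = 5), "post_ms")
})

test_that("aligned averages reproduce single events and injected waveforms", {
  tl <- generate_session_timeline(4, c("F", "N", "F", "F"),
                                  lap_duration_stats = c(8, 0), seed = 1)
  spec <- vm_generator_spec(noise_sd = 0, spike_rate = 0, seed = 1)
  tr <- generate_vm_trace(spec, tl, inject_novelty_on = "FN")
  av <- teleportation_aligned_average(tr, tl, "FN", window = c(1, 3))
  expect_equal(av$n_events, 1)
  w <- novelty_waveform(spec$novelty_amplitude, spec$novelty_decay,
                        spec$sampling_rate)
  post <- av$mean_trace[av$time >= 0][seq_len(2000)]
  expect_lt(max(abs(post - w[seq_len(2000)])), 1e-6)
  pre <- av$mean_trace[av$time < 0]
  expect_lt(max(abs(pre)), 1e-9)
  expect_error(teleportation_aligned_average(tr, tl, "NN"), "NN")
})

test_that("FF alignment on no-injection data is flat within noise", {
  recs <- generate_recording_set(2, vm_generator_spec(), n_laps = 24,
                                 inject_novelty_on = character(0), seed = 11)
  r <- recs[[1]]
  av <- teleportation_aligned_average(r$trace, r$timeline, "FF",
                                      window = c(1, 1))
  expect_gt(av$n_events, 3)
  expect_true(mean(abs(av$mean_trace) < 4 * av$sem_trace) > 0.85)
  expect_lt(abs(mean(av$mean_trace[av$time > 0])), 0.5)
})

test_that("delta-Vm recovers constructed steps exactly and flags edge events", {
  fs <- 1000
  tl <- generate_session_timeline(3, c("F", "F", "F"),
                                  lap_duration_stats = c(4, 0), seed = 1)
  tel <- tl$time_s[tl$kind == "teleport"][1]
  v <- rep(-70, round(attr(tl, "duration") * fs))
  v[(floor(tel * fs) + 1):length(v)] <- -68          # +2 mV step at teleport
  d <- compute_delta_vm(vm_trace(v, fs), tl, "FF")
  expect_equal(d$per_event$delta_vm[1], 2, tolerance = 1e-12)

  # zero-noise, no transient
  tr0 <- generate_vm_trace(vm_generator_spec(noise_sd = 0, spike_rate = 0,
                                             seed = 1), tl,
                           inject_novelty_on = character(0))
  expect_equal(compute_delta_vm(tr0, tl, "FF")$delta_vm, 0)

  # event whose window passes the end of a truncated trace is skipped
  tl2 <- generate_session_timeline(4, c("F", "F", "F", "F"),
                                   lap_duration_stats = c(4, 0), seed = 1)
  tel2 <- tl2$time_s[tl2$kind == "teleport"][2]
  short <- vm_trace(rep(-70, floor((tel2 + 0.5) * fs)), fs)
  expect_warning(compute_delta_vm(short, tl2, "FF"), "skipped")
})

test_that("aligned averaging is linear in the trace", {
  tl <- generate_session_timeline(4, lap_duration_stats = c(5, 0), seed = 2)
  spec <- vm_generator_spec(spike_rate = 0)
  a <- generate_vm_trace(spec, tl, seed = 1)
  b <- generate_vm_trace(spec, tl, seed = 2)
  ab <- vm_trace(a$samples + b$samples, a$sampling_rate)
  av_a <- teleportation_aligned_average(a, tl, "FN", window = c(1, 1))
  av_b <- teleportation_aligned_average(b, tl, "FN", window = c(1, 1))
  av_ab <- teleportation_aligned_average(ab, tl, "FN", window = c(1, 1))
  expect_equal(av_ab$mean_trace, av_a$mean_trace + av_b$mean_trace,
               tolerance = 1e-9)
})

test_that("delta-Vm estimation is unbiased over repeated synthetic datasets", {
  spec <- vm_generator_spec(sampling_rate = 250)
  est <- vapply(seq_len(200), function(k) {
    tl <- generate_session_timeline(6, c("F", "F", "N", "N", "F", "N"),
                                    lap_duration_stats = c(4, 0.2),
                                    seed = 1000 + k)
    tr <- generate_vm_trace(spec, tl, seed = 2000 + k)
    compute_delta_vm(remove_spikes(tr)$trace, tl, "FN")$delta_vm
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - spec$novelty_amplitude), 2 * se + 1e-6)
})

test_that("the FN-vs-FF test is calibrated under the null", {
  spec <- vm_generator_spec(sampling_rate = 250, spike_rate = 0)
  n_rep <- 500
  rej <- vapply(seq_len(n_rep), function(k) {
    dd <- vapply(seq_len(9), function(cell) {
      tl <- generate_session_timeline(8, lap_duration_stats = c(4, 0.2),
                                      seed = 10000 + 97 * k + cell)
      tr <- generate_vm_trace(spec, tl, inject_novelty_on = character(0),
                              seed = 20000 + 97 * k + cell)
      c(compute_delta_vm(tr, tl, "FN")$delta_vm,
        compute_delta_vm(tr, tl, "FF")$delta_vm)
    }, numeric(2))
    run_stat("wilcoxon_signed_rank", dd[1, ], dd[2, ])$p_value < 0.05
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(sum(rej), ci[1] - 1)
  expect_lte(sum(rej), ci[2] + 1)
})

test_that("nonparametric wrappers match their contracts", {
  expect_error(run_stat("wilcoxon_signed_rank", 1:5, 1:5), "zero")
  expect_error(run_stat("wilcoxon_signed_rank", 1:4, 1:5), "equal length")

  set.seed(1)
  a <- rnorm(50); b <- rnorm(50, 2)
  st <- run_stat("mann_whitney_u", a, b)
  expect_lt(st$p_value, 0.001)

  st3 <- run_stat("mann_whitney_u", a, b, n_comparisons = 3)
  expect_equal(st3$corrected_p, min(1, st3$p_value * 3))

  m <- matrix(rnorm(30), 10, 3)
  stf <- run_stat("friedman", m)
  expect_true(stf$p_value >= 0 && stf$p_value <= 1)
})
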