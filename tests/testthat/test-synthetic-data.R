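# Synthetic-data generator: session structure, baseline distribution,
# transient calibration, and behavioural sessions.

test_that("teleportation types follow the consecutive-environment pair rule", {
  tl <- generate_session_timeline(3, c("F", "F", "F"), seed = 1)
  tel <- tl[tl$kind == "teleport", ]
  expect_equal(nrow(tel), 2)
  expect_equal(tel$teleport_type, c("FF", "FF"))

  tl <- generate_session_timeline(4, c("F", "N", "N", "F"), seed = 1)
  expect_equal(tl$teleport_type[tl$kind == "teleport"], c("FN", "NN", "NF"))

  expect_error(generate_session_timeline(2, c("F", "X")), "index 2")
})

test_that("timelines are deterministic, time-sorted, and reset position at teleports", {
  a <- generate_session_timeline(20, seed = 7)
  b <- generate_session_timeline(20, seed = 7)
  expect_identical(a, b)
  expect_false(is.unsorted(a$time_s))
  expect_true(all(a$position_cm[a$kind == "teleport"] == 0))
})

test_that("skew-normal baseline sampler has the requested moments", {
  v <- sample_baseline_vm(1000, -73, 9, 4, seed = 1)
  expect_lt(abs(mean(v) + 73), 3 * 9 / sqrt(1000))
  v2 <- sample_baseline_vm(2e4, -73, 9, 4, seed = 2)
  expect_lt(abs(sd(v2) - 9), 0.2)

  # shape 0 reduces to an ordinary Gaussian: sample skewness near zero
  g <- sample_baseline_vm(5e4, -73, 9, 0, seed = 3)
  skw <- mean((g - mean(g))^3) / sd(g)^3
  expect_lt(abs(skw), 0.05)

  expect_error(sample_baseline_vm(10, sd = 0), "sd")
})

test_that("subsample extremes match an independent rejection-sampler oracle", {
  # expected min/max of subsamples of 26, on the -90..-50 mV scale
  set.seed(42)
  n_rep <- 400
  oracle <- sn_moment_correct(rsn_reject(26 * n_rep, 4), -73, 9, 4)
  om <- matrix(oracle, 26)
  ours <- matrix(sample_baseline_vm(26 * n_rep, -73, 9, 4, seed = 9), 26)
  exp_min <- mean(apply(om, 2, min)); exp_max <- mean(apply(om, 2, max))
  expect_lt(abs(mean(apply(ours, 2, min)) - exp_min), 1)
  expect_lt(abs(mean(apply(ours, 2, max)) - exp_max), 1.5)
  # the published bracket for n = 26 recordings
  expect_lt(exp_min, -85); expect_gt(exp_min, -95)
  expect_lt(exp_max, -45); expect_gt(exp_max, -55)
})

test_that("novelty waveform is calibrated so its 1-s mean equals the amplitude", {
  for (amp in c(0.5, 1.02, 5)) {
    w <- novelty_waveform(amp, 0.8, 1000)
    expect_equal(mean(w[1:1000]), amp, tolerance = 1e-12)
  }
  # visibly outlasts 2 s only in its tail: < 10% of peak after 2 s
  w <- novelty_waveform(1.02, 0.8, 1000)
  expect_lt(w[2000] / w[1], 0.1)
})

test_that("noiseless transient injection yields an exact delta-Vm", {
  tl <- generate_session_timeline(4, c("F", "N", "F", "N"),
                                  lap_duration_stats = c(6, 0), seed = 1)
  spec <- vm_generator_spec(noise_sd = 0, spike_rate = 0,
                            novelty_amplitude = 5, seed = 2)
  tr <- generate_vm_trace(spec, tl, inject_novelty_on = "FN")
  d <- compute_delta_vm(tr, tl, "FN")
  expect_equal(d$delta_vm, 5, tolerance = 1e-9)
  d0 <- compute_delta_vm(tr, tl, "NF")
  expect_lt(abs(d0$delta_vm), 0.02)   # only the decayed tail of the transient
})

test_that("the additive transient leaves window variance essentially unchanged", {
  spec <- vm_generator_spec(seed = 1)
  w <- novelty_waveform(spec$novelty_amplitude, spec$novelty_decay,
                        spec$sampling_rate)
  post <- w[1:spec$sampling_rate]
  noise_var <- spec$noise_sd^2
  expect_lt(var(post), 0.05 * noise_var)
})

test_that("no injection means FF and FN windows are statistically equal", {
  recs <- generate_recording_set(6, vm_generator_spec(), n_laps = 12,
                                 inject_novelty_on = character(0), seed = 5)
  d <- delta_vm_by_cell(recs, "FN")
  d0 <- delta_vm_by_cell(recs, "FF")
  st <- run_stat("wilcoxon_signed_rank", d$delta_vm, d0$delta_vm)
  expect_gt(st$p_value, 0.05)
})

test_that("trace generation is reproducible and rejects unknown teleport types", {
  tl <- generate_session_timeline(4, seed = 1)
  spec <- vm_generator_spec(seed = 3)
  a <- generate_vm_trace(spec, tl)
  b <- generate_vm_trace(spec, tl)
  expect_identical(a$samples, b$samples)
  expect_error(generate_vm_trace(spec, tl, inject_novelty_on = "XY"),
               "unknown teleportation type")
})

test_that("behavioural hit rate hits its floor, ceiling, and binomial regime", {
  expect_equal(hit_rate(generate_behaviour_session(20, anticipation_prob = 1,
                                                   seed = 1)), 1)
  expect_equal(hit_rate(generate_behaviour_session(20, anticipation_prob = 0,
                                                   lick_rate = 0, seed = 1)), 0)
  hr <- hit_rate(generate_behaviour_session(200, anticipation_prob = 0.5,
                                            seed = 2))
  expect_lt(abs(hr - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("timeline CSV round-trips through the plain-text format", {
  tl <- generate_behaviour_session(5, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_session_timeline(tl, path)
  back <- read_session_timeline(path)
  expect_equal(as.data.frame(back)$time_s, as.data.frame(tl)$time_s)
  expect_equal(hit_rate(back), hit_rate(tl))
})
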