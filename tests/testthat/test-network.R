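# CA3 network construction and dynamics, checked against brute-force oracles
# at small scale.

test_that("place-field assignment covers the requested fraction", {
  cfg <- toy_ca3_config()
  pf <- assign_place_fields(cfg, "F", seed = 1)
  expect_length(pf$units, round(0.8 * 50))
  expect_true(all(!is.na(pf$centres[pf$units])))
  expect_true(all(is.na(pf$centres[-pf$units])))

  pf_all <- assign_place_fields(toy_ca3_config(place_fraction = 1), "F",
                                seed = 1)
  expect_length(pf_all$units, 50)

  expect_error(assign_place_fields(toy_ca3_config(place_fraction = 0.05), "F"),
               "unconstructible")
})

test_that("per-position candidate pools match the counting expectation", {
  cfg <- ca3_config(n = 2000, p = 100, pf_diameter = 13, pattern_size = 33)
  counts <- replicate(20, {
    pf <- assign_place_fields(cfg, "F")
    cc <- pf$centres[pf$units]
    mean(vapply(40:60, function(mu) sum(abs(cc - mu) <= 6), numeric(1)))
  })
  expected <- round(0.2 * 2000) * 13 / 100
  expect_lt(abs(mean(counts) - expected), 3)
})

test_that("patterns have exact weight, PF-consistent support, and determinism", {
  cfg <- ca3_config(n = 600, p = 40, pattern_size = 20, pf_diameter = 9,
                    place_fraction = 0.5, inputs_per_unit = 100)
  pf <- assign_place_fields(cfg, "F", seed = 2)
  pat <- generate_patterns(pf, cfg, seed = 3)
  expect_equal(unname(Matrix::colSums(pat$patterns)), rep(20, 40))
  # support within PF-overlapping units at every position
  for (mu in c(1, 20, 40)) {
    act <- which(pat$patterns[, mu] > 0)
    expect_true(all(abs(pf$centres[act] - mu) <= 4))
  }
  pat2 <- generate_patterns(assign_place_fields(cfg, "F", seed = 2), cfg,
                            seed = 3)
  expect_identical(as.matrix(pat$patterns), as.matrix(pat2$patterns))
})

test_that("patterns at positions beyond one field diameter share no units", {
  cfg <- ca3_config(n = 600, p = 40, pattern_size = 20, pf_diameter = 9,
                    place_fraction = 0.5, inputs_per_unit = 100)
  pat <- generate_patterns(assign_place_fields(cfg, "F", seed = 4), cfg,
                           seed = 5)
  X <- as.matrix(pat$patterns)
  expect_equal(sum(X[, 10] * X[, 30]), 0)   # disjoint candidate pools
  expect_gt(sum(X[, 10] * X[, 11]), 1)      # adjacent patterns correlated
})

test_that("clipped Hebbian couplings equal the brute-force rule", {
  cfg <- toy_ca3_config()
  pat <- generate_patterns(assign_place_fields(cfg, "F", seed = 1), cfg,
                           seed = 2)
  J <- as.matrix(build_coupling_F(pat))
  X <- as.matrix(pat$patterns)
  J_brute <- matrix(0, cfg$n, cfg$n)
  for (i in seq_len(cfg$n)) for (j in seq_len(cfg$n)) {
    J_brute[i, j] <- min(1, sum(X[i, ] * X[j, ]))
  }
  expect_equal(J, J_brute)
  expect_true(isSymmetric(J))

  # p = 1: clipping inactive, coupling is the outer product of the pattern
  cfg1 <- toy_ca3_config(p = 1, pf_diameter = 5)
  pat1 <- generate_patterns(assign_place_fields(cfg1, "F", seed = 3), cfg1,
                            seed = 4)
  x <- as.numeric(pat1$patterns[, 1])
  expect_equal(as.matrix(build_coupling_F(pat1)), outer(x, x))
})

test_that("pre-map couplings follow their scenario's law", {
  # prewired: nonzero weights are Beta(0.7, 1.2) distributed
  cfg <- ca3_config(n = 2000, p = 50, pattern_size = 40, pf_diameter = 13,
                    place_fraction = 0.5, inputs_per_unit = 100)
  pat <- generate_patterns(assign_place_fields(cfg, "N", seed = 5), cfg,
                           seed = 6)
  J_N <- build_coupling_N(cfg, pat, seed = 7)
  w <- J_N@x
  expect_true(all(w > 0 & w < 1))
  ks <- suppressWarnings(stats::ks.test(w, function(q) pbeta(q, 0.7, 1.2)))
  expect_gt(ks$p.value, 0.001)

  # random: integer unit-strength couplings with Gaussian in-degree
  cfg_r <- ca3_config(n = 2000, p = 50, pattern_size = 40, pf_diameter = 13,
                      place_fraction = 0.2, inputs_per_unit = 100,
                      scenario = "random")
  pat_r <- generate_patterns(assign_place_fields(cfg_r, "N", seed = 8), cfg_r,
                             seed = 9)
  J_r <- build_coupling_N(cfg_r, pat_r, seed = 10)
  expect_true(all(J_r@x == 1))
  indeg <- Matrix::rowSums(J_r)[pat_r$units]
  expect_lt(abs(mean(indeg) - 20), 3 * 3 / sqrt(length(indeg)) + 0.5)
  # support confined to the assembly
  expect_true(all(Matrix::rowSums(J_r)[-pat_r$units] == 0))
})

test_that("connectivity has exact in-degree and no self-connections", {
  cfg <- toy_ca3_config(inputs_per_unit = 20)
  C <- build_connectivity(cfg, seed = 1)
  expect_true(all(Matrix::rowSums(C) == 20))
  expect_true(all(Matrix::diag(C) == 0))

  # complete graph minus diagonal
  cfg_full <- toy_ca3_config(n = 12, inputs_per_unit = 11)
  C2 <- as.matrix(build_connectivity(cfg_full, seed = 2))
  expect_equal(C2, matrix(1, 12, 12) - diag(12))

  # column sums concentrate around the binomial mean
  cfg_m <- ca3_config(n = 1000, inputs_per_unit = 100, pattern_size = 20,
                      p = 50, pf_diameter = 13)
  C3 <- build_connectivity(cfg_m, seed = 3)
  cs <- Matrix::colSums(C3)
  expect_lt(abs(mean(cs) - 100), 1e-9)
  expect_lt(abs(sd(cs) - sqrt(1000 * 0.1 * 0.9)), 3)
})

test_that("the activation sigmoid hits its exact landmarks", {
  expect_equal(activation_probability(2.31), 0.5, tolerance = 1e-12)
  expect_equal(activation_probability(2.31 + 0.1), 0.75, tolerance = 1e-12)
  expect_lt(activation_probability(-1e6), 1e-5)
  expect_gt(activation_probability(1e6), 1 - 1e-5)
  h <- seq(-5, 10, by = 0.1)
  expect_true(all(diff(activation_probability(h)) > 0))
})

test_that("input components equal a naive per-unit summation oracle", {
  cfg <- toy_ca3_config(n = 100, p = 10, pattern_size = 12, pf_diameter = 5,
                        inputs_per_unit = 30)
  net <- build_ca3_network(cfg, seed = 11)
  state <- init_network_state(net, "F", 5L)
  set.seed(1)
  state$h_mec_F <- rnorm(100)^2
  state$h_dg_base <- rbinom(100, 1, 0.1) * 2
  state$h_dg_inhib <- net$A_dg_inhib
  inp <- compute_inputs(state, net)

  Jm <- as.matrix(net$J)
  s <- as.numeric(state$s)
  h_rc_naive <- vapply(seq_len(100), function(i) sum(Jm[i, ] * s), numeric(1))
  expect_equal(inp$h_rc, h_rc_naive, tolerance = 1e-12)
  S_naive <- max(cfg$S_min, sum(s))
  expect_equal(inp$S, S_naive)
  expect_equal(inp$total,
               h_rc_naive - net$g * S_naive + state$h_mec_F + state$h_mec_N +
                 state$h_dg_base + state$h_dg_excit - state$h_dg_inhib,
               tolerance = 1e-12)
})

test_that("cue decay and the quiescent fixed point behave as designed", {
  cfg <- toy_ca3_config(n = 100, p = 10, pattern_size = 12, pf_diameter = 5,
                        inputs_per_unit = 30, S_min = 50)
  net <- build_ca3_network(cfg, seed = 12)
  state <- init_network_state(net, "F", 1L, s = rep(FALSE, 100))
  state$h_mec_F[1] <- 3
  set.seed(2)
  state <- step_network(state, net)
  expect_equal(state$h_mec_F[1], 3 * exp(-1 / cfg$tau_mEC), tolerance = 1e-12)

  # zero couplings, zero cues: mean activity n * L(-g * S_min)
  net0 <- net
  net0$J <- net$J * 0
  state0 <- init_network_state(net0, "F", 1L, s = rep(FALSE, 100))
  set.seed(3)
  acts <- replicate(400, {
    state0 <<- step_network(state0, net0)
    sum(state0$s)
  })
  expected <- sum(activation_probability(-net$g * cfg$S_min, cfg$G, cfg$T))
  expect_lt(abs(mean(acts) - expected), 4 * sd(acts) / sqrt(length(acts)) + 0.5)
})

test_that("near-zero noise makes the update a deterministic threshold", {
  cfg <- toy_ca3_config(n = 100, p = 10, pattern_size = 12, pf_diameter = 5,
                        inputs_per_unit = 30, T = 1e-9)
  net <- build_ca3_network(cfg, seed = 13)
  state <- init_network_state(net, "F", 5L)
  inp <- compute_inputs(state, net)
  set.seed(4)
  state2 <- step_network(state, net)
  expect_identical(state2$s, inp$total > cfg$G)
})

test_that("full-scale constructions satisfy their exact count identities", {
  cfg <- ca3_config()
  pf <- assign_place_fields(cfg, "F", seed = 1)
  expect_length(pf$units, 4000)
  expect_equal(cfg$sparsity, 330 / 20000)
})
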