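# Protocol construction and the stochastic trace simulator

test_that("the standard step protocol has 17 levels over ~53 s", {
  p <- build_protocol(0.2, -0.2, -0.025)
  expect_equal(p$n_levels, 17)
  expect_equal(p$levels_V[1], 0.2)
  expect_equal(p$levels_V[17], -0.2)
  expect_equal(diff(p$levels_V), rep(-0.025, 16))
  expect_equal(p$total_stepped_s, 52.7)
  expect_equal(round(p$total_stepped_s), 53)
})

test_that("protocol validation rejects non-commensurate ranges", {
  expect_error(build_protocol(0.2, -0.2, -0.03), "multiple")
  expect_error(build_protocol(0.2, -0.2, 0.025), "multiple")
  expect_error(build_protocol(0.2, -0.2, 0), "non-zero")
  expect_equal(build_protocol(0.1, 0.1, -0.025)$n_levels, 1)
})

test_that("gating trajectories honour limits and determinism", {
  pe <- patch_energetics()
  gk <- gating_kinetics(0.03)
  # no pores: all-zero series
  g0 <- simulate_gating(pe, gk, 0, 0.1, 0.5, seed = 1)
  expect_true(all(g0$n_open == 0))
  # absorbing open limit: K -> Inf keeps every pore open
  pe_open <- pore_energetics(-900, 0, 0)
  g1 <- simulate_gating(pe_open, gk, 5, 0.1, 0.5, seed = 1)
  expect_true(all(g1$n_open == 5))
  # identical seeds give identical trajectories
  ga <- simulate_gating(pe, gk, 10, 0.15, 1, seed = 42)
  gb <- simulate_gating(pe, gk, 10, 0.15, 1, seed = 42)
  expect_identical(ga$n_open, gb$n_open)
})

test_that("time-averaged open fraction matches the stationary law", {
  pe <- patch_energetics()
  gk <- gating_kinetics(0.03)
  set.seed(11)
  for (v in c(0.2, 0.15, 0.1)) {
    g <- simulate_gating(pe, gk, 10, v, 10, sample_rate_Hz = 1000)
    p <- open_probability(pe, v)
    se <- occupancy_se(p, g$k_open_per_s, g$k_close_per_s, 10, 10)
    expect_lt(abs(g$open_fraction - p), 3 * se)
  }
})

test_that("empirical dwell means match the generating rates", {
  pe <- pore_energetics(0, 0, 0)  # P = 1/2: equal open/closed rates
  gk <- gating_kinetics(0.02)
  g <- simulate_gating(pe, gk, 20, 0.1, 5, seed = 7, sample_rate_Hz = 1000)
  expect_gt(length(g$dwells$open), 1000)
  mo <- mean(g$dwells$open)
  mc <- mean(g$dwells$closed)
  expect_lt(abs(mo - 0.02), 3 * 0.02 / sqrt(length(g$dwells$open)))
  expect_lt(abs(mc - 1 / g$k_open_per_s),
            3 * (1 / g$k_open_per_s) / sqrt(length(g$dwells$closed)))
})

test_that("noise-free pore-free trace is the constant leak current", {
  proto <- build_protocol(0.1, 0.1, -0.025, step_s = 0.5)
  cs <- conductance_set(g_leak_S = 372e-12)
  tr <- simulate_trace(proto, cs, patch_energetics(), recording_env(),
                       gating_kinetics(), tp = NULL, nm = NULL, seed = 1)
  x <- tr[[1]]
  step_idx <- x$time_s >= proto$pre_step_s
  expect_equal(unique(x$current_A[step_idx]), 372e-12 * 0.1)
  expect_equal(unique(x$current_A[!step_idx]), 0)
})

test_that("tail means converge to the two-process conduction law", {
  # many pores, no noise/transient: ensemble average obeys the model
  cs <- conductance_set(g_leak_S = 0.37e-9, g_single_S = 10e-12,
                        n_pores = 150)
  pe <- patch_energetics()
  proto <- build_protocol(0.2, 0.05, -0.075, step_s = 3.1)
  tr <- simulate_trace(proto, cs, pe, recording_env(), gating_kinetics(),
                       tp = NULL, nm = NULL, seed = 5)
  prof <- extract_iv(tr)
  for (j in seq_len(nrow(prof))) {
    v <- prof$voltage_V[j]
    p <- open_probability(pe, v)
    expected <- (0.37e-9 + 1.5e-9 * p) * v
    k_close <- 1 / 0.03
    se_frac <- occupancy_se(p, k_close * p / (1 - p), k_close, 1.5, 150)
    se_i <- se_frac * 150 * 10e-12 * abs(v)
    expect_lt(abs(prof$mean_current_A[j] - expected), 3 * se_i + 1e-15)
  }
})

test_that("the recording filter has unit DC gain", {
  proto <- build_protocol(0.1, 0.1, -0.025, step_s = 2)
  cs <- conductance_set(g_leak_S = 1e-9)
  tr <- simulate_trace(proto, cs, patch_energetics(), recording_env(),
                       gating_kinetics(), tp = NULL,
                       nm = noise_model(current_noise_sd_A = 0,
                                        filter_cutoff_Hz = 2000),
                       seed = 1)
  prof <- extract_iv(tr, window_s = c(1, 2))
  expect_equal(prof$mean_current_A, 1e-9 * 0.1, tolerance = 1e-9)
})

test_that("identical seed and parameters give bit-identical traces", {
  cs <- conductance_set(g_leak_S = 0.3e-9, g_single_S = 30e-12,
                        n_pores = 10)
  proto <- build_protocol(0.2, 0.1, -0.05, step_s = 0.4)
  a <- simulate_trace(proto, cs, patch_energetics(), recording_env(),
                      gating_kinetics(), transient_params(), noise_model(),
                      seed = 9)
  b <- simulate_trace(proto, cs, patch_energetics(), recording_env(),
                      gating_kinetics(), transient_params(), noise_model(),
                      seed = 9)
  for (j in seq_along(a)) expect_identical(a[[j]]$current_A,
                                           b[[j]]$current_A)
})

test_that("patch tails are asymmetric while BLM tails are symmetric", {
  proto <- build_protocol(0.2, -0.2, -0.4, step_s = 2)  # +200/-200 only
  cs <- conductance_set(g_leak_S = 0.3e-9, g_pores_S = 1.5e-9)
  pe <- patch_energetics()
  patch <- extract_iv(simulate_trace(proto, cs, pe, recording_env(),
                                     gating_kinetics(), NULL, NULL,
                                     seed = 1, gating = "mean"))
  expect_gt(abs(patch$mean_current_A[1]), 2 * abs(patch$mean_current_A[2]))
  blm <- extract_iv(simulate_trace(proto, cs, pe, recording_env(),
                                   gating_kinetics(), NULL, NULL,
                                   seed = 1, mode = "blm",
                                   gating = "mean"))
  expect_equal(blm$mean_current_A[1], -blm$mean_current_A[2],
               tolerance = 1e-10)
})

test_that("depth scaling multiplies conductances and labels the result", {
  cs <- conductance_set(g_leak_S = 1e-9, g_single_S = 68e-12, n_pores = 20)
  same <- depth_condition(cs, 1, 1, 1)
  expect_equal(same$g_leak_S, cs$g_leak_S)
  expect_equal(same$g_pores_S, cs$g_pores_S)
  expect_equal(attr(same, "depth_mm"), 1)
  deeper <- depth_condition(cs, 3, g_leak_factor = 1.32,
                            g_pores_factor = 2.0)
  expect_equal(deeper$g_leak_S / cs$g_leak_S, 1.32)
  expect_equal(deeper$g_single_S / cs$g_single_S, 2.0)
  expect_equal(deeper$g_pores_S / cs$g_pores_S, 2.0)
})
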