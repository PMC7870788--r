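# Channel-event idealization, dwell statistics and empirical open
# probability

# single-pore recording at the single-channel study scale: 68 pS at 190 mV
single_channel_trace <- function(seed = 3, noise_sd = 1e-12,
                                 duration = 5, drift = 0) {
  proto <- build_protocol(0.19, 0.19, step_s = duration)
  cs <- conductance_set(g_leak_S = 0, g_single_S = 68e-12, n_pores = 1)
  pe <- pore_energetics(1, 0, 0)  # P_open ~ 0.27, voltage-independent
  simulate_trace(proto, cs, pe, recording_env(), gating_kinetics(0.03),
                 tp = NULL, nm = noise_model(noise_sd, 2000), seed = seed,
                 drift_A_per_s = drift)[[1]]
}

test_that("baseline correction removes injected drift and keeps flat traces", {
  tr <- single_channel_trace()
  flat <- baseline_correct(tr)
  expect_equal(flat$current_A, tr$current_A, tolerance = 0.05)
  # injected 1 pA/s drift is removed to < 0.1 pA/s
  trd <- single_channel_trace(drift = 1e-12)
  corr <- baseline_correct(trd)
  expect_lt(abs(attr(corr, "metadata")$baseline_drift_A_per_s - 1e-12),
            0.1e-12)
  # pure ramp with no gating comes out flat
  t <- seq(0, 2, 1e-4)
  ramp <- current_trace(t, rep(0.1, length(t)), 5e-12 * t,
                        metadata = list(sample_rate_Hz = 1e4))
  out <- baseline_correct(ramp)
  expect_lt(diff(range(out$current_A)), 0.2e-12)
})

test_that("a constant trace idealizes to no events and one level", {
  t <- seq(0, 1, 1e-4)
  ct <- current_trace(t, rep(0.1, length(t)), rep(50e-12, length(t)),
                      metadata = list(sample_rate_Hz = 1e4))
  el <- idealize(ct, settle_s = 0)
  expect_equal(nrow(el$events), 0)
  expect_equal(el$n_levels, 1)
})

test_that("noise-free square waves are idealized to the sample", {
  fs <- 1e4
  t <- seq(0, 2 - 1 / fs, 1 / fs)
  x <- rep(0, length(t))
  # open periods [0.2, 0.35), [0.8, 1.0), [1.5, 1.62)
  on <- list(c(0.2, 0.35), c(0.8, 1.0), c(1.5, 1.62))
  for (p in on) x[t >= p[1] & t < p[2]] <- 13e-12
  x <- x + rnorm(length(t), 0, 1e-16)  # break the degenerate density
  tr <- current_trace(t, rep(0.19, length(t)), x,
                      metadata = list(sample_rate_Hz = fs))
  el <- idealize(tr, settle_s = 0)
  expect_equal(nrow(el$events), 3)
  expect_equal(el$events$start_s, c(0.2, 0.8, 1.5), tolerance = 2 / fs)
  expect_equal(el$events$end_s, c(0.35, 1.0, 1.62), tolerance = 2 / fs)
  expect_equal(el$step_amplitude_A, 13e-12, tolerance = 0.02)
})

test_that("idealization recovers the simulated step size and event count", {
  tr <- single_channel_trace(seed = 3)
  el <- idealize(baseline_correct(tr))
  true_step <- 68e-12 * 0.19  # 12.92 pA
  expect_lt(abs(el$step_amplitude_A - true_step) / true_step, 0.10)
  n_true <- attr(tr, "metadata")$true_openings
  expect_lt(abs(nrow(el$events) - n_true) / n_true, 0.20)
})

test_that("step estimates are invariant to offset and drift", {
  tr <- single_channel_trace(seed = 5)
  el0 <- idealize(baseline_correct(tr))
  shifted <- tr
  shifted$current_A <- shifted$current_A + 94e-12 +
    1e-12 * (shifted$time_s - shifted$time_s[1])
  el1 <- idealize(baseline_correct(shifted))
  expect_equal(el1$step_amplitude_A, el0$step_amplitude_A,
               tolerance = 0.05)
  expect_equal(single_channel_conductance(el1$step_amplitude_A, 0.19),
               single_channel_conductance(el0$step_amplitude_A, 0.19),
               tolerance = 0.05)
})

test_that("two superposed channels produce three conduction levels", {
  proto <- build_protocol(0.19, 0.19, step_s = 8)
  cs <- conductance_set(g_leak_S = 0, g_single_S = 68e-12, n_pores = 2)
  pe <- pore_energetics(0, 0, 0)  # P_open = 1/2: all levels well visited
  tr <- simulate_trace(proto, cs, pe, recording_env(),
                       gating_kinetics(0.05), tp = NULL,
                       nm = noise_model(1e-12, 2000), seed = 11)[[1]]
  el <- idealize(baseline_correct(tr))
  expect_equal(el$n_levels, 3)
  expect_true(any(el$events$level_index == 2))
})

test_that("dwell-time statistics match the gating generator", {
  # a single event of 50 ms has mean open dwell 50 ms
  el1 <- structure(list(events = data.frame(start_s = 0.1, end_s = 0.15,
                                            level_index = 1L,
                                            amplitude_A = 13e-12),
                        duration_s = 1, sample_rate_Hz = 1e4),
                   class = "event_list")
  st <- dwell_time_stats(el1)
  expect_equal(st$open$mean_s, 0.05)
  expect_equal(st$open$n, 1)
  # empty event list: zero counts
  el0 <- structure(list(events = data.frame(start_s = numeric(0),
                                            end_s = numeric(0),
                                            level_index = integer(0),
                                            amplitude_A = numeric(0))),
                   class = "event_list")
  expect_equal(dwell_time_stats(el0)$open$n, 0)
  # long simulated recording: empirical mean within 3 SE of 20 ms
  proto <- build_protocol(0.19, 0.19, step_s = 40)
  cs <- conductance_set(g_leak_S = 0, g_single_S = 68e-12, n_pores = 1)
  pe <- pore_energetics(0.5, 0, 0)
  tr <- simulate_trace(proto, cs, pe, recording_env(),
                       gating_kinetics(0.02), tp = NULL,
                       nm = noise_model(1e-12, 2000), seed = 17)[[1]]
  st2 <- dwell_time_stats(idealize(baseline_correct(tr)))
  expect_gt(st2$open$n, 500)
  # events shorter than the 2 ms dead time are censored; by memorylessness
  # the retained exponential dwells have mean (dead time + true mean)
  expect_lt(abs(st2$open$mean_s - (0.02 + 0.002)),
            3 * 0.02 / sqrt(st2$open$n) + 0.002)
})

test_that("empirical open probability tracks the stationary law", {
  # degenerate limits from hand-built event lists
  mk <- function(open_s, v) structure(
    list(events = if (open_s > 0)
      data.frame(start_s = 0, end_s = open_s, level_index = 1L,
                 amplitude_A = 1e-12)
      else data.frame(start_s = numeric(0), end_s = numeric(0),
                      level_index = integer(0), amplitude_A = numeric(0)),
      duration_s = 1, open_time_s = open_s, mean_level = open_s,
      voltage_V = v, n_pores = 1L),
    class = "event_list")
  tab <- empirical_open_probability(list(mk(0, 0.1), mk(1, 0.2)))
  expect_equal(tab$p_any_open, c(0, 1))
  # simulated family: per-pore open fraction within 3 SE of P_open(V)
  pe <- pore_energetics(2, 40, 0)
  cs <- conductance_set(g_leak_S = 0, g_single_S = 68e-12, n_pores = 1)
  gk <- gating_kinetics(0.03)
  els <- lapply(c(0.15, 0.19), function(vv) {
    tr <- simulate_trace(build_protocol(vv, vv, step_s = 30), cs, pe,
                         recording_env(), gk, tp = NULL,
                         nm = noise_model(1e-12, 2000),
                         seed = round(1e3 * vv))[[1]]
    idealize(baseline_correct(tr))
  })
  tab2 <- empirical_open_probability(els)
  for (j in seq_len(nrow(tab2))) {
    p <- open_probability(pe, tab2$voltage_V[j])
    k_close <- 1 / 0.03
    se <- occupancy_se(p, k_close * p / (1 - p), k_close, 30, 1)
    expect_lt(abs(tab2$p_per_pore[j] - p), 3 * se + 0.01)
  }
})
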