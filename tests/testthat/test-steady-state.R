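# I-V extraction and two-process model fitting

make_series <- function(..., gating = "mean") {
  simulate_trace(build_protocol(), patch_conductances(),
                 patch_energetics(), recording_env(), gating_kinetics(),
                 ..., seed = 1, gating = gating)
}

test_that("offset correction subtracts the holding-segment mean", {
  tr <- make_series(tp = NULL, nm = NULL)[[3]]
  # constant injected offset cancels exactly
  shifted <- tr
  shifted$current_A <- shifted$current_A + 5e-12
  corr <- correct_offset(shifted)
  expect_equal(corr$current_A, correct_offset(tr)$current_A)
  # an already-zero holding segment is untouched
  expect_equal(correct_offset(tr)$current_A, tr$current_A)
  # with noise, the holding mean after correction is zero within SE
  trn <- make_series(tp = NULL, nm = noise_model(2e-12, NULL))[[3]]
  trn$current_A <- trn$current_A + 5e-12
  corr <- correct_offset(trn)
  rel <- corr$time_s - corr$time_s[1]
  hold <- rel >= 0.025 & rel < 0.05
  expect_lt(abs(mean(corr$current_A[hold])),
            3 * 2e-12 / sqrt(sum(hold)) + 1e-18)
  bad <- current_trace(1:10 / 1e4, rep(0.1, 10), rep(0, 10),
                       metadata = list(sample_rate_Hz = 1e4))
  expect_error(correct_offset(bad), "holding segment")
})

test_that("extract_iv averages the tail window per level", {
  tr <- make_series(tp = NULL, nm = NULL)
  prof <- extract_iv(tr)
  expect_s3_class(prof, "iv_profile")
  expect_equal(nrow(prof), 17)
  # noise-free model traces reproduce the conduction law exactly
  pe <- patch_energetics()
  expected <- steady_state_current(patch_conductances(), pe,
                                   recording_env(), prof$voltage_V)
  expect_equal(prof$mean_current_A, expected, tolerance = 1e-12)
  expect_true(all(prof$sd_current_A < 1e-18))
  # constant traces: mean equals the constant, sd = 0
  ct <- current_trace(seq(0, 3.1499, 1e-4), rep(0.1, 31500),
                      rep(7e-12, 31500),
                      metadata = list(pre_step_s = 0.05, step_s = 3.1,
                                      level_V = 0.1,
                                      sample_rate_Hz = 1e4))
  p1 <- extract_iv(list(ct))
  expect_equal(p1$mean_current_A, 7e-12)
  expect_equal(p1$sd_current_A, 0)
  # first-level exclusion leaves 16 usable points
  prof2 <- extract_iv(tr, discard_first = TRUE)
  expect_equal(sum(!prof2$excluded), 16)
  expect_true(prof2$excluded[1])
  expect_error(extract_iv(tr, window_s = c(3.5, 4)), "window")
})

test_that("linear fit recovers a pure leak conductance", {
  v <- seq(-0.2, 0.2, 0.025)
  prof <- iv_profile(v, 372e-12 * v)
  f <- fit_linear(prof)
  expect_equal(coef(f)[["g_leak_S"]], 372e-12, tolerance = 1e-12)
  expect_equal(f$scenario, "linear")
  # all-zero currents give zero conductance
  expect_equal(coef(fit_linear(iv_profile(v, 0 * v)))[["g_leak_S"]], 0)
  # noisy recovery within 3 SE
  set.seed(3)
  profn <- iv_profile(v, 372e-12 * v + rnorm(17, 0, 2e-12))
  fn <- fit_linear(profn)
  expect_lt(abs(coef(fn)[["g_leak_S"]] - 372e-12), 3 * fn$se[["g_leak_S"]])
  expect_error(fit_linear(iv_profile(0.1, 1e-12)), "2 usable")
})

test_that("noise-free profiles return the generating parameters", {
  pe <- patch_energetics()
  cs <- patch_conductances()
  v <- seq(-0.2, 0.2, 0.025)
  prof <- iv_profile(v, steady_state_current(cs, pe, recording_env(), v))
  f <- fit_iv(prof, "free_leak")
  cf <- coef(f)
  expect_equal(cf[["g_leak_S"]], 0.37e-9, tolerance = 1e-4)
  expect_equal(cf[["g_pores_S"]], 1.5e-9, tolerance = 1e-3)
  expect_equal(cf[["offset_V"]], 0.2, tolerance = 1e-3)
  expect_equal(cf[["dmu0_kT"]], 4, tolerance = 1e-3)
  expect_equal(cf[["alpha_kT_per_V2"]], 40, tolerance = 1e-2)
  # reported minimum open probability is P_open at -V0
  expect_equal(cf[["p_min"]],
               open_probability(pore_energetics(cf[["dmu0_kT"]],
                                                cf[["alpha_kT_per_V2"]],
                                                cf[["offset_V"]]),
                                -cf[["offset_V"]]),
               tolerance = 1e-8)
  # fixed-leak scenario with the true leak also recovers the pore term
  ffix <- fit_iv(prof, "fixed_leak", fixed_g_leak_S = 0.37e-9)
  expect_equal(coef(ffix)[["g_pores_S"]], 1.5e-9, tolerance = 1e-3)
  expect_error(fit_iv(prof, "fixed_leak"), "fixed_g_leak_S")
  expect_error(fit_iv(prof[1:4, ], "free_leak"), "6 usable")
})

test_that("nesting: free leak never fits worse than pores only", {
  pe <- patch_energetics()
  cs <- patch_conductances()
  v <- seq(-0.2, 0.2, 0.025)
  set.seed(8)
  for (k in 1:3) {
    prof <- iv_profile(v, steady_state_current(cs, pe, recording_env(), v) +
                         rnorm(17, 0, 2e-12))
    f_free <- fit_iv(prof, "free_leak")
    f_pores <- fit_iv(prof, "pores_only")
    expect_lte(f_free$rss, f_pores$rss * (1 + 1e-6))
    expect_equal(coef(f_pores)[["g_leak_S"]], 0)
  }
})

test_that("symmetric data yield a near-zero fitted offset and odd fit", {
  pe <- blm_energetics()
  cs <- conductance_set(g_leak_S = 270e-12, g_pores_S = 863e-12)
  v <- seq(-0.2, 0.2, 0.025)
  set.seed(21)
  prof <- iv_profile(v, steady_state_current(cs, pe, recording_env(), v) +
                       rnorm(17, 0, 2e-12))
  f <- fit_iv(prof, "free_leak")
  expect_lt(abs(coef(f)[["offset_V"]]), 0.010)
  vg <- seq(0.05, 0.2, 0.01)
  expect_equal(predict(f, -vg), -predict(f, vg), tolerance = 0.05)
})

test_that("iv_fit methods are mutually consistent", {
  pe <- patch_energetics()
  cs <- patch_conductances()
  v <- seq(-0.2, 0.2, 0.025)
  prof <- iv_profile(v, steady_state_current(cs, pe, recording_env(), v))
  f <- fit_iv(prof, "free_leak")
  expect_equal(fitted(f), predict(f))
  expect_equal(residuals(f), prof$mean_current_A - fitted(f))
  expect_output(print(f), "free_leak")
  expect_output(print(summary(f)), "Minimum open probability")
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "iv_profile")
  # excluded-point sanity: restoring the flagged point cannot reduce the
  # RSS of the fit evaluated on the originally usable points
  prof2 <- prof
  prof2$excluded[1] <- TRUE
  f2 <- fit_iv(prof2, "free_leak")
  rss_kept <- sum((prof2$mean_current_A[-1] - predict(f2)[-1])^2)
  f_all <- fit_iv(prof, "free_leak")
  rss_all_on_kept <- sum((prof$mean_current_A[-1] - predict(f_all)[-1])^2)
  expect_gte(rss_all_on_kept, rss_kept - 1e-30)
})

test_that("negative-slope detection flags the gated negative branch", {
  # strictly increasing: empty result
  v <- seq(-0.2, 0.2, 0.025)
  expect_equal(nrow(detect_negative_slope(iv_profile(v, 1e-9 * v))), 0)
  # monotone decreasing artificial profile: one interval covering it
  dec <- detect_negative_slope(iv_profile(v, -1e-9 * v))
  expect_equal(nrow(dec), 1)
  expect_equal(dec$v_from_V, min(v))
  expect_equal(dec$v_to_V, max(v))
  # strong gating with an offset produces a negative-slope region on the
  # negative branch of the 17-level grid
  pe <- pore_energetics(1, 100, 0.2)
  cs <- conductance_set(g_leak_S = 0.1e-9, g_pores_S = 5e-9)
  prof <- iv_profile(v, steady_state_current(cs, pe, recording_env(), v))
  ns <- detect_negative_slope(prof)
  expect_gt(nrow(ns), 0)
  expect_true(all(ns$v_to_V < 0))
  expect_error(detect_negative_slope(iv_profile(v[1:2], v[1:2] * 1e-9)),
               "3 usable")
})

test_that("depth comparison reports percent changes in the conductances", {
  pe <- patch_energetics()
  v <- seq(-0.2, 0.2, 0.025)
  base <- conductance_set(g_leak_S = 1e-9, g_pores_S = 1.5e-9)
  fit_at <- function(cs) {
    prof <- iv_profile(v, steady_state_current(cs, pe, recording_env(), v))
    fit_iv(prof, "free_leak")
  }
  f1 <- fit_at(base)
  # identical fits: zero percent change
  same <- compare_depths(list(`1mm` = f1, also = f1))
  expect_equal(same$changes$g_leak_pct, 0, tolerance = 1e-6)
  expect_equal(same$changes$g_pores_pct, 0, tolerance = 1e-6)
  # scaling by (1.32, 1.37) is recovered as +32% / +37%
  deeper <- depth_condition(base, 3, g_leak_factor = 1.32,
                            g_pores_factor = 1.37)
  f3 <- fit_at(deeper)
  cmp <- compare_depths(list(`1mm` = f1, `3mm` = f3))
  expect_equal(cmp$changes$g_leak_pct, 32, tolerance = 0.01)
  expect_equal(cmp$changes$g_pores_pct, 37, tolerance = 0.01)
  expect_equal(cmp$summary$v0_mean_V, c(0.2, 0.2), tolerance = 0.005)
})
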