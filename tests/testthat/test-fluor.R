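make_series <- function(metal_total, intensity = rep(0, length(metal_total)),
                        C_P = 1e-5, C_L = 5e-4, pH = 6, ...) {
  fluor_series(metal_total, intensity,
               design = list(C_P = C_P, C_L = C_L, pH = pH,
                             temperature = 298, ...))
}

test_that("binding isotherms evaluate to their closed forms", {
  expect_equal(response_one_site(0, 3.7e6, -1), 0)
  # half-saturation at [M] = 1/K
  expect_equal(response_one_site(1 / 3.7e6, 3.7e6, -1), -0.5)
  expect_equal(response_one_site(1e-6, 3.7e6, -1), -3.7 / 4.7,
               tolerance = 1e-12)
  m <- 10 ^ seq(-9, -4, 0.25)
  r <- response_one_site(m, 3.7e6, -1)
  expect_true(all(diff(r) < 0))          # strictly monotone
  expect_true(all(r >= -1 & r <= 0))     # bounded by the amplitude

  # two-site: saturation limit, nesting, direct evaluation
  expect_equal(response_two_site(1, 3.5e7, 7.4e6, -0.6, -1), -1,
               tolerance = 1e-6)
  expect_equal(response_two_site(m, 3.5e7, 0, -0.6, -1),
               response_one_site(m, 3.5e7, -0.6), tolerance = 1e-12)
  expect_equal(response_two_site(1e-7, 3.5e7, 7.4e6, -0.6, -1),
               (-2.1 - 2.59) / 7.09, tolerance = 1e-12)
})

test_that("two-site response converges to one-site as K2 vanishes", {
  K1 <- 3.5e7
  m <- 10 ^ seq(-9, -5, 0.2)
  delta <- max(abs(response_two_site(m, K1, 1e-6 * K1 * 1e-6, 0.6, 1) -
                     response_one_site(m, K1, 0.6)))
  expect_lt(delta, 1e-4)
  deltas <- vapply(10 ^ c(-2, -4, -6), function(eps)
    max(abs(response_two_site(m, K1, eps * K1, 0.6, 1) -
              response_one_site(m, K1, 0.6))), numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("baseline subtraction requires and uses the metal-free point", {
  s <- make_series(c(0, 1e-6, 2e-6), intensity = c(100, 80, 60))
  expect_equal(delta_F(s), c(0, 20, 40))
  s2 <- make_series(c(0, 1e-6, 2e-6), intensity = c(50, 50, 50))
  expect_equal(delta_F(s2), c(0, 0, 0))
  s3 <- make_series(c(0, 1e-6, 2e-6), intensity = c(50, 60, 70))
  expect_equal(delta_F(s3), c(0, -10, -20))   # rising signal stays signed
  s4 <- fluor_series(c(1e-7, 1e-6), c(90, 80),
                     design = list(C_P = 1e-5, C_L = 0, pH = 6,
                                   temperature = 298))
  expect_error(delta_F(s4), "baseline")
})

test_that("predicted curves respect saturation and competition", {
  K1 <- 1e7; amp <- 1e7; C_P <- 1e-5
  mt <- c(0, 10 ^ seq(-6.5, -3.5, length.out = 12))
  s <- make_series(mt, C_P = C_P, C_L = 0)
  p_free <- predict_fluor(list(kind = "one-site", K1 = K1, amp1 = amp), s)
  expect_equal(max(p_free), amp * C_P, tolerance = 1e-3)  # saturates

  s_ch <- make_series(mt, C_P = C_P, C_L = 5e-4)
  p_ch <- predict_fluor(list(kind = "one-site", K1 = K1, amp1 = amp), s_ch,
                        chelator = ida_default())
  expect_true(all(p_ch[-1] < p_free[-1]))  # competition lowers every point
})

test_that("predicted free metal matches per-point bisection at the assay design", {
  sc <- scenario_library()$fluor_CaM_Y_II
  d <- sc$design
  s <- make_series(d$metal_total, C_P = d$C_P, C_L = d$C_L, pH = d$pH)
  pars <- list(kind = "one-site", K1 = 3.7e6, amp1 = 1e7)
  p <- predict_fluor(pars, s, sc$chelator)
  m_nr <- attr(p, "free_M")
  pep <- peptide_model(1, 3.7e6)
  for (i in seq_along(m_nr)) {
    m_o <- oracle_free_metal(
      component_totals(d$metal_total[i], d$C_L, d$C_P, pH = d$pH),
      sc$chelator, pep)
    if (m_o > 0) expect_equal(m_nr[i], m_o, tolerance = 1e-8)
  }
  expect_true(all(diff(p) > 0))  # quenching grows monotonically
})

test_that("per-step volumes produce the expected dilution factors", {
  mt <- c(0, 10 ^ seq(-6.5, -4, length.out = 9))
  vols <- c(0, rep(4, 9))
  pars <- list(kind = "one-site", K1 = 1e7, amp1 = 1e7)
  s0 <- make_series(mt, C_P = 1e-5, C_L = 0)
  s1 <- fluor_series(mt, rep(0, 10),
                     design = list(C_P = 1e-5, C_L = 0, pH = 6,
                                   temperature = 298, V0_uL = 800),
                     added_volume_uL = vols)
  tot0 <- coopbind:::.fluor_point_totals(s0)
  tot1 <- coopbind:::.fluor_point_totals(s1)
  expect_equal(tot1$C_P / tot0$C_P, 800 / (800 + cumsum(vols)),
               tolerance = 1e-12)
  # at saturation the predicted signal scales with the diluted C_P
  p0 <- predict_fluor(pars, s0)
  p1 <- predict_fluor(pars, s1)
  expect_equal(p1[10] / p0[10], 800 / (800 + sum(vols)), tolerance = 1e-3)
})

test_that("noise-free one-site fits recover the constant to high precision", {
  mt <- c(0, 10 ^ seq(-6.8, -4.3, length.out = 14))
  s <- make_series(mt, C_P = 1e-5, C_L = 1e-4)
  truth <- list(kind = "one-site", K1 = 2.3e7, amp1 = 8e6)
  dF <- predict_fluor(truth, s, ida_default())
  s$intensity <- 1000 - as.numeric(dF)
  fit <- fit_fluor(s, "one-site", ida_default(),
                   control = fit_control(assume_no_dilution = TRUE))
  est <- fit$fits[[1]]$estimates
  expect_equal(unname(est["log10_K1"]), log10(2.3e7), tolerance = 1e-6)
  expect_equal(unname(est["amp1"]), 8e6, tolerance = 1e-6)
})

test_that("model nesting orders residuals and is flagged by the F-check", {
  sc <- scenario_library()$fluor_CaM_Y_I_II
  reps <- gen_fluor(sc, noise_model("relative", 0.01, seed = 31), 1)
  ctrl <- fit_control(assume_no_dilution = TRUE)
  f2 <- fit_fluor(reps, "two-site", sc$chelator, control = ctrl)
  f1 <- fit_fluor(reps, "one-site", sc$chelator, control = ctrl)
  expect_lt(f2$fits[[1]]$rss, f1$fits[[1]]$rss)

  # one-site data offered to the two-site model: F-check warns
  sc1 <- scenario_library()$fluor_CaM_Y_II
  reps1 <- gen_fluor(sc1, noise_model("relative", 0.02, seed = 5), 1)
  expect_warning(
    fit_fluor(reps1, "two-site", sc1$chelator, control = ctrl),
    "one-site")
})

test_that("missing per-step volumes trigger the dilution warning once", {
  sc <- scenario_library()$fluor_CaM_Y_II
  reps <- gen_fluor(sc, noise_model("relative", 0.01, seed = 9), 1)
  expect_warning(fit_fluor(reps, "one-site", sc$chelator),
                 "dilution")
})

test_that("replicate summaries aggregate constants geometrically with natural-scale SD", {
  sc <- scenario_library()$fluor_CaM_Y_II
  reps <- gen_fluor(sc, noise_model("relative", 0.01, seed = 13), 3)
  fit <- fit_fluor(reps, "one-site", sc$chelator,
                   control = fit_control(assume_no_dilution = TRUE))
  s <- fit$summary
  expect_identical(unique(s$sd_source), "replicates")
  lk1 <- vapply(fit$fits, function(f) f$estimates[["log10_K1"]], numeric(1))
  # geometric mean across replicates, consistent with the log10_K1 row
  expect_equal(s$mean[s$parameter == "K1"], 10 ^ mean(lk1))
  expect_equal(s$mean[s$parameter == "log10_K1"], mean(lk1))
  expect_equal(s$sd[s$parameter == "K1"], sd(10 ^ lk1))
})
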