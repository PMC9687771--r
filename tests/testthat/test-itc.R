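std_design <- function(...) {
  itc_design(V0_uL = 200, syringe_P = 1e-3, cell_M = 1e-4, cell_L = 2e-4,
             injection_volumes_uL = c(0.4, rep(2, 19)), ...)
}

test_that("injection bookkeeping follows the displacement model", {
  d0 <- itc_design(200, 1e-3, 1e-4, 2e-4, injection_volumes_uL = 2)
  conc <- injection_concentrations(d0)
  expect_equal(conc$peptide[1], 0)
  expect_equal(conc$metal[1], 1e-4)      # no injections yet
  expect_equal(conc$peptide[2], 1e-3 * 0.01 / 1.005, tolerance = 1e-12)
  expect_equal(conc$metal[2], 1e-4 * 0.995 / 1.005, tolerance = 1e-12)

  conc_full <- injection_concentrations(std_design())
  expect_true(all(diff(conc_full$peptide) > 0))
  expect_true(all(diff(conc_full$metal) < 0))

  big <- itc_design(200, 1e-3, 1e-4, 2e-4, rep(10, 12))
  expect_warning(injection_concentrations(big), "half the cell volume")
})

test_that("one-site heats obey limits and telescope", {
  d <- std_design()
  ch <- ida_default()
  expect_equal(as.numeric(predict_heats_one_site(d, 4.2e6, 0, ch)),
               rep(0, 20))

  # stoichiometric regime: each 2 uL injection of 1e-3 M peptide binds fully
  dd <- itc_design(200, 1e-3, 1e-2, 0, injection_volumes_uL = rep(2, 5))
  q <- predict_heats_one_site(dd, 1e12, -10)
  expect_equal(as.numeric(q)[1], -20, tolerance = 0.02)

  q2 <- predict_heats_one_site(d, 4.2e6, -2.0, ch)
  st <- attr(q2, "states")
  total <- -2.0 * (d$V0_uL / 1e6) * (st$MP[nrow(st)] - st$MP[1]) * 1e9
  expect_equal(sum(q2), total, tolerance = 1e-6)
})

test_that("two-site heats superpose and telescope", {
  d <- itc_design(200, 2e-3, 2e-4, 4e-4, c(0.4, rep(2, 19)))
  ch <- ida_default()
  p0 <- itc_model_params(4e7, 4.2e6, 5.7e6, 0, 0, 0)
  expect_equal(as.numeric(predict_heats_two_site(d, p0, ch)), rep(0, 20))

  # independent sites (K2 = KI KII / (KI + KII), dH_c = 0): the heats equal
  # the per-site occupancy heats computed from the joint free-metal series
  KI <- 4e7; KII <- 4.2e6
  K2_ind <- KI * KII / (KI + KII)
  pp <- itc_model_params(KI, KII, K2_ind, -40.2, -2.0, 0)
  q <- predict_heats_two_site(d, pp, ch)
  st <- attr(q, "states")
  occI <- KI * st$free_M / (1 + KI * st$free_M)
  occII <- KII * st$free_M / (1 + KII * st$free_M)
  q_site <- -40.2 * coopbind:::.dn_uJ_per_kJ(occI * st$peptide, d$V0_uL) +
    -2.0 * coopbind:::.dn_uJ_per_kJ(occII * st$peptide, d$V0_uL)
  expect_equal(as.numeric(q), q_site, tolerance = 1e-6)

  # telescoping with cooperativity switched on
  set.seed(21)
  for (i in 1:5) {
    pr <- itc_model_params(10 ^ runif(1, 6, 8), 10 ^ runif(1, 5, 7),
                           10 ^ runif(1, 5, 7), runif(1, -50, 0),
                           runif(1, -20, 0), runif(1, -10, 30))
    qq <- predict_heats_two_site(d, pr, ch)
    stq <- attr(qq, "states")
    n <- nrow(stq)
    fI <- pr$KI / (pr$KI + pr$KII)
    expected <- (d$V0_uL / 1e6) * 1e9 *
      (pr$dH_I * fI * (stq$MP[n] - stq$MP[1]) +
         pr$dH_II * (1 - fI) * (stq$MP[n] - stq$MP[1]) +
         (pr$dH_I + pr$dH_II + pr$dH_c) * (stq$M2P[n] - stq$M2P[1]))
    expect_equal(sum(qq), expected, tolerance = 1e-6)
  }
})

test_that("blank subtraction is elementwise and unit-safe", {
  v <- rep(2, 6)
  s <- itc_series(c(-5, -4, -3, -2, -1, 0), v, "uJ")
  expect_equal(subtract_blank(s, s)$heats, rep(0, 6))
  z <- itc_series(rep(0, 6), v, "uJ")
  expect_equal(subtract_blank(s, z)$heats, s$heats)
  s_cal <- itc_series(s$heats, v, "ucal")
  expect_error(subtract_blank(s_cal, z), "unit")
  expect_error(subtract_blank(s, itc_series(0, 2, "uJ")), "same number")
})

test_that("microcalorie series convert on the way into the fitters", {
  expect_equal(coopbind:::.heats_uJ(itc_series(c(-1, -2), c(2, 2), "ucal")),
               c(-4.184, -8.368))
})

test_that("one-site ITC fits recover noise-free parameters", {
  sc <- scenario_library()$itc_CaM_Y_II
  d <- gen_itc(sc, noise_model("absolute", 0, 2), n_replicates = 1)
  corr <- subtract_blank(d[[1]]$sample, d[[1]]$blank)
  fit <- fit_itc_one_site(corr, sc$design, sc$chelator)
  s <- fit$summary
  expect_equal(s$mean[s$parameter == "K"], 4.2e6, tolerance = 1e-4)
  expect_equal(s$mean[s$parameter == "dH"], -2.0, tolerance = 1e-4)
  expect_false(fit$unidentifiable)
})

test_that("all-zero heats are flagged unidentifiable", {
  sc <- scenario_library()$itc_CaM_Y_II
  z <- itc_series(rep(0, 20), sc$design$injection_volumes_uL, "uJ")
  fit <- fit_itc_one_site(z, sc$design, sc$chelator)
  s <- fit$summary
  expect_equal(s$mean[s$parameter == "dH"], 0, tolerance = 1e-8)
  expect_true(fit$unidentifiable)
})

test_that("two-site ITC fit recovers all four free parameters", {
  sc <- scenario_library()$itc_CaM_Y_I_II
  tr <- sc$truth
  d <- gen_itc(sc, noise_model("absolute", 0, 3), n_replicates = 1)
  corr <- subtract_blank(d[[1]]$sample, d[[1]]$blank)
  fit <- fit_itc_two_site(corr, sc$design, sc$chelator,
                          fixed = list(KII = tr$KII, dH_II = tr$dH_II),
                          sensitivity = TRUE)
  s <- fit$summary
  g <- function(p) s$mean[s$parameter == p]
  expect_equal(g("KI"), tr$KI, tolerance = 0.01)
  expect_equal(g("K2"), tr$K2, tolerance = 0.01)
  expect_equal(g("dH_I"), tr$dH_I, tolerance = 0.01)
  expect_equal(g("dH_c"), tr$dH_c, tolerance = 0.01)
  # derived macroscopic K1 closes against the generator's constants
  expect_equal(fit$derived$K1, tr$KI + tr$KII, tolerance = 0.01)
  # perturbing the fixed site II parameters shifts the fit, and the
  # sensitivity table reports it
  expect_true(!is.null(fit$sensitivity))
  expect_true(any(abs(fit$sensitivity$shift) > 0))
})
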