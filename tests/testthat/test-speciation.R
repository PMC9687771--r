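test_that("side-reaction coefficient follows the protonation sum", {
  expect_identical(side_reaction_coefficient(numeric(), 6), 1)
  # pKa equal to pH: protonated and deprotonated populations are equal
  expect_equal(side_reaction_coefficient(6.0, 6), 2.0)
  # term-by-term: 1 + 10^(9.3-6) + 10^(9.3+2.6-12)
  expect_equal(side_reaction_coefficient(c(9.3, 2.6), 6),
               1 + 10^3.3 + 10^-0.1, tolerance = 1e-12)
  expect_error(side_reaction_coefficient(c(2.6, 9.3), 6), "highest first")
  # monotonically non-increasing in pH
  alphas <- vapply(seq(2, 12, 0.5), side_reaction_coefficient,
                   numeric(1), pKa = c(9.34, 2.61, 1.82))
  expect_true(all(diff(alphas) <= 0))
  expect_true(all(alphas >= 1))
})

test_that("conditional constants divide beta by alpha^q", {
  ch <- chelator_model(pKa = numeric(),
                       species = data.frame(m = 1, l = 1, log10_beta = 8))
  expect_equal(conditional_constants(ch, 6)$log10_beta_cond, 8)  # alpha = 1
  ch2 <- chelator_model(pKa = 8,
                        species = data.frame(m = c(1, 1), l = c(1, 2),
                                             log10_beta = c(8, 16)))
  a <- side_reaction_coefficient(8, 6)
  cc <- conditional_constants(ch2, 6)
  expect_equal(cc$log10_beta_cond, c(8 - log10(a), 16 - 2 * log10(a)),
               tolerance = 1e-12)
})

test_that("speciation solves closed-form systems exactly", {
  # no reactions: free metal equals the total
  st <- solve_speciation(component_totals(metal = 1e-5))
  expect_equal(unname(st$free["metal"]), 1e-5)

  # equal totals, one-site peptide: K m^2 + m - C = 0
  K <- 1e6; C <- 1e-5
  st <- solve_speciation(component_totals(metal = C, peptide = C),
                         peptide = peptide_model(1, K))
  m_exact <- (-1 + sqrt(1 + 4 * K * C)) / (2 * K)
  expect_equal(unname(st$free["metal"]), m_exact, tolerance = 1e-10)
  expect_true(st$converged)

  # symmetric chelator/peptide competition: x^2 + 11 x - 10 = 0, x = K m
  ch <- chelator_model(numeric(),
                       data.frame(m = 1, l = 1, log10_beta = 6))
  st <- solve_speciation(component_totals(1e-5, 1e-5, 1e-5),
                         chelator = ch, peptide = peptide_model(1, 1e6))
  x <- (-11 + sqrt(121 + 40)) / 2
  expect_equal(unname(st$free["metal"]), x / 1e6, tolerance = 1e-9)
})

test_that("invalid speciation inputs are rejected", {
  expect_error(component_totals(metal = -1e-6), "non-negative")
  expect_error(component_totals(1e-5, pH = 15), "pH")
  expect_error(chelator_model(c(2, 9), data.frame(m = 1, l = 1,
                                                  log10_beta = 8)),
               "highest first")
  expect_error(chelator_model(numeric(), data.frame(m = integer(),
                                                    l = integer(),
                                                    log10_beta = numeric())),
               "at least one")
  expect_error(peptide_model(2, 1e6), "K2")
})

test_that("mass-balance residuals behave as diagnostics", {
  pep <- peptide_model(1, 1e6)
  tot <- component_totals(1e-5, 0, 1e-5)
  st <- solve_speciation(tot, peptide = pep)
  r <- mass_balance_residuals(st, tot, peptide = pep)
  expect_true(all(abs(r) <= 1e-10))

  # doubling the free metal over-reconstructs the metal total
  st2 <- st
  st2$free["metal"] <- 2 * st$free["metal"]
  r2 <- mass_balance_residuals(st2, tot, peptide = pep)
  expect_lt(r2[["metal"]], 0)
  expect_gt(abs(r2[["metal"]]), 0)

  # empty system
  tot0 <- component_totals(0, 0, 0)
  st0 <- solve_speciation(tot0)
  expect_equal(unname(mass_balance_residuals(st0, tot0)), c(0, 0, 0))
})

test_that("Newton-Raphson agrees with the nested-bisection oracle", {
  set.seed(42)
  for (i in 1:30) {
    sys <- random_system()
    st <- solve_speciation(sys$totals, sys$chelator, sys$peptide)
    m_oracle <- oracle_free_metal(sys$totals, sys$chelator, sys$peptide)
    expect_equal(unname(st$free["metal"]), m_oracle, tolerance = 1e-8)
  }
})

test_that("free metal is monotone in the component totals", {
  ch <- ida_default()
  pep <- peptide_model(2, 3.5e7, 7.4e6)
  base <- c(metal = 2e-5, chelator = 5e-4, peptide = 1e-5)
  fm <- function(tm, tl, tp)
    unname(solve_speciation(component_totals(tm, tl, tp, pH = 6),
                            ch, pep)$free["metal"])
  grid <- seq(0.5, 2, length.out = 5)
  m_up <- vapply(grid * base["metal"], fm, numeric(1),
                 tl = base["chelator"], tp = base["peptide"])
  expect_true(all(diff(m_up) > 0))
  m_ch <- vapply(grid * base["chelator"], function(tl)
    fm(base["metal"], tl, base["peptide"]), numeric(1))
  expect_true(all(diff(m_ch) < 0))
  m_pep <- vapply(grid * base["peptide"], function(tp)
    fm(base["metal"], base["chelator"], tp), numeric(1))
  expect_true(all(diff(m_pep) < 0))
})

test_that("joint scaling of totals and constants preserves bound fractions", {
  set.seed(7)
  for (i in 1:5) {
    sys <- random_system()
    st1 <- solve_speciation(sys$totals, sys$chelator, sys$peptide)
    fac <- 10 ^ stats::runif(1, -1, 1)
    tot2 <- component_totals(sys$totals$metal * fac,
                             sys$totals$chelator * fac,
                             sys$totals$peptide * fac,
                             pH = sys$totals$pH)
    # dividing every association constant by fac: for a species with total
    # stoichiometry s the cumulative constant scales by fac^-(s-1)
    sp <- sys$chelator$species
    sp$log10_beta <- sp$log10_beta - (sp$m + sp$l - 1) * log10(fac)
    ch2 <- chelator_model(sys$chelator$pKa, sp)
    pep2 <- if (sys$peptide$n_sites == 1)
      peptide_model(1, sys$peptide$K1 / fac)
    else peptide_model(2, sys$peptide$K1 / fac, sys$peptide$K2 / fac)
    st2 <- solve_speciation(tot2, ch2, pep2)
    f1 <- 1 - st1$free[["metal"]] / sys$totals$metal
    f2 <- 1 - st2$free[["metal"]] / tot2$metal
    expect_equal(f1, f2, tolerance = 1e-8)
  }
})

test_that("speciation output table round-trips through disk", {
  st <- solve_speciation(component_totals(1e-5, 5e-4, 1e-5, pH = 6),
                         chelator = ida_default(),
                         peptide = peptide_model(1, 3.7e6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_speciation(st, path)
  tbl <- read.csv(path)
  expect_setequal(tbl$species, c("M", "L", "P", names(st$species)))
  expect_equal(tbl$concentration_M[tbl$species == "MP"],
               unname(st$species["MP"]), tolerance = 1e-15)
})
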