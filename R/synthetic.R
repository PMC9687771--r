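# Synthetic titration generator: named scenarios mimicking the experimental
# designs of the uranyl/calmodulin competition study (peptide + IDA
# fluorescence titrations; reverse-titration ITC), with true parameters of
# the magnitudes reported there. Used by every recovery test; no external
# data are required.

#' Measurement-noise model
#'
#' @param kind `"absolute"` (sd in signal units) or `"relative"` (sd as a
#'   fraction of the signal amplitude, i.e. of the largest absolute model
#'   value in the series).
#' @param sd Standard deviation (units or fraction), >= 0.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(kind = c("relative", "absolute"), sd = 0.01,
                        seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(sd >= 0)
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

.noise_sd <- function(noise, signal) {
  if (noise$kind == "absolute") noise$sd else noise$sd * max(abs(signal), 0)
}

#' Library of paper-mimicking titration scenarios
#'
#' Named records pairing an experimental design with true parameters, for
#' fluorescence (one-site, two-site and phosphorylated two-site peptides;
#' peptide 1e-5 M with 5e-4 M chelator, or the more dilute phosphorylated
#' designs) and ITC (one- and two-site reverse titrations, 200 uL cell,
#' 0.4 uL + 19 x 2 uL injections, peptide 1-2e-3 M in the syringe). True
#' constants and enthalpies have the magnitudes reported for the
#' corresponding calmodulin N-terminal-domain variants. Fluorescence
#' amplitudes are in arbitrary intensity units per mol/L of peptide
#' (quenching positive); the default titrant schedule is 20 logarithmically
#' spaced metal totals from 0 to 4 peptide equivalents.
#'
#' @param chelator The competing-chelator model used by every scenario;
#'   defaults to [ida_default()].
#' @return A named list of `"titration_scenario"` objects, each with fields
#'   `name`, `type` (`"fluor"` or `"itc"`), `kind` (`"one-site"` or
#'   `"two-site"`), `design`, `truth` and `chelator`.
#' @export
scenario_library <- function(chelator = ida_default()) {
  fluor_design <- function(C_P, C_L, pH, n_points = 20, max_eq = 4) {
    eq <- c(0, 10 ^ seq(log10(0.08), log10(max_eq), length.out = n_points - 1))
    list(C_P = C_P, C_L = C_L, pH = pH, temperature = 298,
         metal_total = eq * C_P)
  }
  itc_design_std <- function(syr_P, cell_M, cell_L) {
    itc_design(V0_uL = 200, syringe_P = syr_P, cell_M = cell_M,
               cell_L = cell_L, injection_volumes_uL = c(0.4, rep(2, 19)),
               pH = 6, temperature = 298)
  }
  sc <- function(name, type, kind, design, truth) {
    structure(list(name = name, type = type, kind = kind, design = design,
                   truth = truth, chelator = chelator),
              class = "titration_scenario")
  }
  list(
    fluor_CaM_Y_II = sc(
      "fluor_CaM_Y_II", "fluor", "one-site",
      fluor_design(1e-5, 5e-4, pH = 6),
      list(K1 = 3.7e6, amp1 = 1e7)),
    fluor_CaM_YW_II = sc(
      "fluor_CaM_YW_II", "fluor", "one-site",
      fluor_design(1e-5, 5e-4, pH = 6),
      list(K1 = 5.1e6, amp1 = 1e7)),
    fluor_CaM_Y_I_II = sc(
      "fluor_CaM_Y_I_II", "fluor", "two-site",
      fluor_design(1e-5, 5e-4, pH = 6),
      list(K1 = 3.5e7, K2 = 7.4e6, amp1 = 6e6, amp2 = 1e7)),
    fluor_CaM_YW_I_II = sc(
      "fluor_CaM_YW_I_II", "fluor", "two-site",
      fluor_design(1e-5, 5e-4, pH = 6),
      list(K1 = 7.4e7, K2 = 9.7e6, amp1 = 6e6, amp2 = 1e7)),
    fluor_CaM1_Y_I_II_P_pH6 = sc(
      "fluor_CaM1_Y_I_II_P_pH6", "fluor", "two-site",
      fluor_design(5e-6, 5e-4, pH = 6),
      list(K1 = 3.6e8, K2 = 7.8e7, amp1 = 6e6, amp2 = 1e7)),
    fluor_CaM1_YW_I_II_P_pH7 = sc(
      "fluor_CaM1_YW_I_II_P_pH7", "fluor", "two-site",
      fluor_design(5e-7, 5e-5, pH = 7),
      list(K1 = 6.0e11, K2 = 5.1e9, amp1 = 6e6, amp2 = 1e7)),
    itc_CaM_Y_II = sc(
      "itc_CaM_Y_II", "itc", "one-site",
      itc_design_std(1e-3, 1e-4, 2e-4),
      list(K = 4.2e6, dH = -2.0)),
    itc_CaM_YW_II = sc(
      "itc_CaM_YW_II", "itc", "one-site",
      itc_design_std(1e-3, 1e-4, 2e-4),
      list(K = 4.9e6, dH = -8.9)),
    itc_CaM_Y_I_II = sc(
      "itc_CaM_Y_I_II", "itc", "two-site",
      itc_design_std(2e-3, 2e-4, 4e-4),
      list(KI = 4.0e7, KII = 4.2e6, K2 = 5.7e6,
           dH_I = -40.2, dH_II = -2.0, dH_c = 25.0)),
    itc_CaM_YW_I_II = sc(
      "itc_CaM_YW_I_II", "itc", "two-site",
      itc_design_std(2e-3, 2e-4, 4e-4),
      list(KI = 5.8e7, KII = 4.9e6, K2 = 7.8e6,
           dH_I = -34.8, dH_II = -8.9, dH_c = 3.8))
  )
}

# noise-free model curve of a fluorescence scenario
.fluor_truth_series <- function(scenario) {
  d <- scenario$design
  ser <- fluor_series(d$metal_total, rep(0, length(d$metal_total)),
                      design = list(C_P = d$C_P, C_L = d$C_L, pH = d$pH,
                                    temperature = d$temperature))
  params <- c(scenario$truth, list(kind = scenario$kind))
  dF <- predict_fluor(params, ser, scenario$chelator)
  list(series = ser, dF = dF)
}

#' Generate synthetic fluorescence titrations
#'
#' The noise-free curve equals [predict_fluor()] under the scenario's true
#' parameters exactly; Gaussian noise is then added per point to the
#' intensities. Replicates differ only by the noise stream; identical seeds
#' give bit-identical datasets.
#'
#' @param scenario A fluorescence entry of [scenario_library()].
#' @param noise A [noise_model()].
#' @param n_replicates Number of replicate series.
#' @param F0 Metal-free baseline intensity (arbitrary units).
#' @return A list of [fluor_series()] objects.
#' @export
gen_fluor <- function(scenario, noise = noise_model("relative", 0.01),
                      n_replicates = 3, F0 = 1000) {
  stopifnot(inherits(scenario, "titration_scenario"),
            scenario$type == "fluor")
  tr <- .fluor_truth_series(scenario)
  sdv <- .noise_sd(noise, tr$dF)
  set.seed(noise$seed)
  lapply(seq_len(n_replicates), function(r) {
    eps <- stats::rnorm(length(tr$dF), 0, sdv)
    fluor_series(tr$series$metal_total, F0 - as.numeric(tr$dF) + eps,
                 design = tr$series$design)
  })
}

#' Generate synthetic ITC titrations with paired blanks
#'
#' Sample heats are model heats plus a constant per-injection dilution heat
#' plus Gaussian noise; the paired blank carries the same dilution heat with
#' an independent noise stream, so [subtract_blank()] recovers the model
#' heats in expectation.
#'
#' @param scenario An ITC entry of [scenario_library()].
#' @param noise A [noise_model()]; the default 0.5 uJ absolute reflects
#'   typical integrated-heat scatter.
#' @param dilution_heat Constant dilution/mixing heat per injection (uJ).
#' @param n_replicates Number of replicate experiments.
#' @return A list of length `n_replicates`; each element is a list with
#'   `sample` and `blank` [itc_series()] objects (uJ).
#' @export
gen_itc <- function(scenario, noise = noise_model("absolute", 0.5),
                    dilution_heat = 0, n_replicates = 3) {
  stopifnot(inherits(scenario, "titration_scenario"), scenario$type == "itc")
  d <- scenario$design
  q <- if (scenario$kind == "one-site") {
    predict_heats_one_site(d, scenario$truth$K, scenario$truth$dH,
                           scenario$chelator)
  } else {
    predict_heats_two_site(d, do.call(itc_model_params, scenario$truth),
                           scenario$chelator)
  }
  q <- as.numeric(q)
  sdv <- .noise_sd(noise, q)
  set.seed(noise$seed)
  lapply(seq_len(n_replicates), function(r) {
    s <- itc_series(q + dilution_heat + stats::rnorm(length(q), 0, sdv),
                    d$injection_volumes_uL, "uJ")
    b <- itc_series(dilution_heat + stats::rnorm(length(q), 0, sdv),
                    d$injection_volumes_uL, "uJ")
    list(sample = s, blank = b)
  })
}

# truth vector on the reporting scale of the fit summaries
.scenario_truth_vector <- function(scenario) {
  tr <- scenario$truth
  if (scenario$type == "fluor") {
    if (scenario$kind == "one-site") c(K1 = tr$K1, amp1 = tr$amp1)
    else c(K1 = tr$K1, K2 = tr$K2, amp1 = tr$amp1, amp2 = tr$amp2)
  } else {
    if (scenario$kind == "one-site") c(K = tr$K, dH = tr$dH)
    else c(KI = tr$KI, dH_I = tr$dH_I, K2 = tr$K2, dH_c = tr$dH_c)
  }
}

# fit one synthetic experiment of a scenario; returns the summary table
.fit_scenario_once <- function(scenario, noise, n_replicates, control) {
  if (scenario$type == "fluor") {
    reps <- gen_fluor(scenario, noise, n_replicates)
    fit <- fit_fluor(reps, kind = scenario$kind,
                     chelator = scenario$chelator, control = control)
  } else {
    reps <- gen_itc(scenario, noise, n_replicates = n_replicates)
    samples <- lapply(reps, function(r) subtract_blank(r$sample, r$blank))
    fit <- if (scenario$kind == "one-site") {
      fit_itc_one_site(samples, scenario$design, scenario$chelator,
                       control = control)
    } else {
      fit_itc_two_site(samples, scenario$design, scenario$chelator,
                       fixed = list(KII = scenario$truth$KII,
                                    dH_II = scenario$truth$dH_II),
                       control = control)
    }
  }
  fit$summary
}

#' Parameter-recovery experiment over seeded synthetic datasets
#'
#' Generates `n_seeds` independent synthetic experiments from a scenario
#' (each with `n_replicates` replicate series), fits each with the matching
#' pipeline, and summarizes per-parameter recovery: median relative bias,
#' relative RMSE, coverage of the +/-2 SD interval around the replicate mean,
#' and (for constants) the median absolute bias on the log10 scale. Fully
#' deterministic given the base seed.
#'
#' @param scenario A [scenario_library()] entry.
#' @param n_seeds Number of independent synthetic experiments.
#' @param noise A [noise_model()]; its seed is the base seed, experiment `i`
#'   uses `seed + i - 1`.
#' @param n_replicates Replicates per experiment.
#' @param control A [fit_control()]; defaults silence the dilution note.
#' @return A list of class `"recovery_summary"` with `scenario`, `n_seeds`,
#'   a per-parameter `summary` data.frame, and the full `estimates` matrix.
#' @export
recovery_experiment <- function(scenario, n_seeds = 50,
                                noise = noise_model("relative", 0.01),
                                n_replicates = 3,
                                control = fit_control(assume_no_dilution = TRUE,
                                                      check_nested = FALSE)) {
  truth <- .scenario_truth_vector(scenario)
  est <- sdm <- matrix(NA_real_, n_seeds, length(truth),
                       dimnames = list(NULL, names(truth)))
  for (i in seq_len(n_seeds)) {
    ni <- noise_model(noise$kind, noise$sd, noise$seed + i - 1L)
    s <- .fit_scenario_once(scenario, ni, n_replicates, control)
    idx <- match(names(truth), s$parameter)
    est[i, ] <- s$mean[idx]
    sdm[i, ] <- s$sd[idx]
  }
  rel <- sweep(est, 2, truth, "/") - 1
  covered <- abs(sweep(est, 2, truth, "-")) <= 2 * sdm
  isK <- grepl("^K", names(truth))
  log_bias <- matrix(NA_real_, n_seeds, length(truth))
  log_bias[, isK] <- log10(est[, isK, drop = FALSE]) -
    matrix(log10(truth[isK]), n_seeds, sum(isK), byrow = TRUE)
  summary <- data.frame(
    parameter = names(truth),
    truth = unname(truth),
    median_rel_bias = apply(rel, 2, stats::median),
    rel_rmse = sqrt(colMeans(rel^2)),
    coverage_2sd = colMeans(covered),
    median_abs_log10_bias = apply(abs(log_bias), 2, stats::median),
    row.names = NULL)
  structure(list(scenario = scenario$name, n_seeds = n_seeds,
                 noise = noise, n_replicates = n_replicates,
                 summary = summary, estimates = est, sds = sdm),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Recovery experiment:", x$scenario, "-", x$n_seeds, "seeds x",
      x$n_replicates, "replicates,", x$noise$kind, "noise sd", x$noise$sd,
      "\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], signif, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
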