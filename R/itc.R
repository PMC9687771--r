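# ITC reverse-titration modeling: peptide injected into metal + chelator.
#
# Heats are modeled per injection as sums of enthalpies times the change in
# moles of each complex, with species concentrations from the speciation
# solver. The two-site model carries a cooperativity enthalpy dH_c on the
# dinuclear complex; the mononuclear pool is partitioned between the two
# sites by KI/(KI+KII) vs KII/(KI+KII). Internal heat unit: microjoule (uJ).

#' ITC experimental design
#'
#' Reverse-titration layout: the peptide sits in the syringe, metal and
#' competing chelator in the cell.
#'
#' @param V0_uL Active cell volume (uL).
#' @param syringe_P Peptide concentration in the syringe (mol/L).
#' @param cell_M,cell_L Metal and chelator concentrations initially in the
#'   cell (mol/L).
#' @param injection_volumes_uL Ordered per-injection volumes (uL).
#' @param pH,temperature Solution conditions.
#' @return An object of class `"itc_design"`.
#' @examples
#' itc_design(200, 1e-3, 1e-4, 2e-4, c(0.4, rep(2, 19)))
#' @export
itc_design <- function(V0_uL, syringe_P, cell_M, cell_L,
                       injection_volumes_uL, pH = 6, temperature = 298) {
  stopifnot(V0_uL > 0, syringe_P >= 0, cell_M >= 0, cell_L >= 0,
            all(injection_volumes_uL > 0))
  structure(list(V0_uL = V0_uL, syringe_P = syringe_P, cell_M = cell_M,
                 cell_L = cell_L,
                 injection_volumes_uL = as.numeric(injection_volumes_uL),
                 pH = pH, temperature = temperature),
            class = "itc_design")
}

#' ITC injection-heat series
#'
#' @param heats Integrated heat per injection.
#' @param volumes_uL Per-injection volumes (uL), same length.
#' @param unit Heat unit tag, `"uJ"` or `"ucal"`.
#' @return An object of class `"itc_series"`.
#' @export
itc_series <- function(heats, volumes_uL, unit = c("uJ", "ucal")) {
  unit <- match.arg(unit)
  stopifnot(length(heats) == length(volumes_uL))
  structure(list(heats = as.numeric(heats),
                 volumes_uL = as.numeric(volumes_uL), unit = unit),
            class = "itc_series")
}

# convert a series' heats to uJ
.heats_uJ <- function(series) {
  if (series$unit == "ucal") series$heats * 4.184 else series$heats
}

#' Component totals in the active cell volume after each injection
#'
#' Perfusion-cell displacement bookkeeping: with cumulative injected volume
#' `d_j` and active cell volume `V0`, material injected from the syringe has
#' total `C_syr * (d_j/V0) / (1 + d_j/(2 V0))` and material initially present
#' has total `C_0 * (1 - d_j/(2 V0)) / (1 + d_j/(2 V0))`.
#'
#' @param design An [itc_design()].
#' @return A `data.frame` with one row per state, starting at the
#'   pre-injection state (`injection = 0`), columns `injection`,
#'   `cumulative_uL`, `peptide`, `metal`, `chelator` (mol/L).
#' @export
injection_concentrations <- function(design) {
  stopifnot(inherits(design, "itc_design"))
  d <- c(0, cumsum(design$injection_volumes_uL))
  if (max(d) > 0.5 * design$V0_uL)
    warning("cumulative injected volume exceeds half the cell volume; ",
            "the displacement model becomes inaccurate", call. = FALSE)
  f <- d / design$V0_uL
  inj_fac <- f / (1 + f / 2)
  res_fac <- (1 - f / 2) / (1 + f / 2)
  data.frame(injection = seq_along(d) - 1L,
             cumulative_uL = d,
             peptide = design$syringe_P * inj_fac,
             metal = design$cell_M * res_fac,
             chelator = design$cell_L * res_fac)
}

# Species concentrations at every injection state for given peptide model.
# Returns data.frame with columns MP, M2P (0 when absent), free_M, C_P.
.itc_states <- function(design, peptide, chelator) {
  conc <- injection_concentrations(design)
  sp <- .speciation_series(cbind(conc$metal, conc$chelator, conc$peptide),
                           design$pH, chelator, peptide)
  conc$MP <- if ("MP" %in% colnames(sp)) sp[, "MP"] else 0
  conc$M2P <- if ("M2P" %in% colnames(sp)) sp[, "M2P"] else 0
  conc$free_M <- sp[, "M"]
  conc
}

# uJ released per injection for a species concentration trajectory:
# dH (kJ/mol) * V0 (L) * d(conc) (mol/L) * 1e9 (uJ/kJ)
.dn_uJ_per_kJ <- function(conc, V0_uL) {
  (V0_uL / 1e6) * diff(conc) * 1e9
}

#' Predict ITC heats for a one-site peptide
#'
#' `Q_j = dH * V0 * ([MP]_j - [MP]_(j-1))`, with [MP] from the speciation of
#' each injection state.
#'
#' @param design An [itc_design()].
#' @param K Association constant (1/M).
#' @param dH Molar binding enthalpy (kJ/mol).
#' @param chelator A [chelator_model()] or `NULL`.
#' @return Heats per injection in uJ, with the state table as attribute
#'   `"states"`.
#' @export
predict_heats_one_site <- function(design, K, dH, chelator = NULL) {
  stopifnot(K > 0)
  st <- .itc_states(design, peptide_model(1, K), chelator)
  structure(dH * .dn_uJ_per_kJ(st$MP, design$V0_uL), states = st)
}

#' Parameters of the two-site cooperative ITC model
#'
#' @param KI,KII Microscopic association constants for the empty molecule
#'   (1/M).
#' @param K2 Second stepwise macroscopic constant (1/M).
#' @param dH_I,dH_II Site enthalpies (kJ/mol).
#' @param dH_c Cooperativity enthalpy (kJ/mol); the dinuclear complex forms
#'   with enthalpy `dH_I + dH_II + dH_c`.
#' @return A list of class `"itc_model_params"`.
#' @export
itc_model_params <- function(KI, KII, K2, dH_I, dH_II, dH_c) {
  stopifnot(KI > 0, KII > 0, K2 > 0)
  structure(list(KI = KI, KII = KII, K2 = K2,
                 dH_I = dH_I, dH_II = dH_II, dH_c = dH_c),
            class = "itc_model_params")
}

#' Predict ITC heats for a two-site cooperative peptide
#'
#' `Q_j = dH_I dn(MP_I) + dH_II dn(MP_II) + (dH_I + dH_II + dH_c) dn(M2P)`,
#' with the mononuclear pool split as `MP_I = MP * KI/(KI+KII)` and the
#' species concentrations from the speciation using the macroscopic
#' constants `K1 = KI + KII` and `K2`.
#'
#' @param design An [itc_design()].
#' @param params An [itc_model_params()].
#' @param chelator A [chelator_model()] or `NULL`.
#' @return Heats per injection in uJ, with the state table as attribute
#'   `"states"`.
#' @export
predict_heats_two_site <- function(design, params, chelator = NULL) {
  stopifnot(inherits(params, "itc_model_params"))
  K1 <- params$KI + params$KII
  st <- .itc_states(design, peptide_model(2, K1, params$K2), chelator)
  fI <- params$KI / K1
  dn_I <- .dn_uJ_per_kJ(st$MP * fI, design$V0_uL)
  dn_II <- .dn_uJ_per_kJ(st$MP * (1 - fI), design$V0_uL)
  dn_2 <- .dn_uJ_per_kJ(st$M2P, design$V0_uL)
  q <- params$dH_I * dn_I + params$dH_II * dn_II +
    (params$dH_I + params$dH_II + params$dH_c) * dn_2
  structure(q, states = st)
}

#' Blank (dilution/mixing) subtraction
#'
#' Elementwise subtraction of a matched blank titration (no metal in the
#' cell) from a sample series. Lengths and units must agree.
#'
#' @param sample,blank [itc_series()] objects.
#' @return The corrected [itc_series()].
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "itc_series"), inherits(blank, "itc_series"))
  if (length(sample$heats) != length(blank$heats))
    stop("sample and blank must have the same number of injections",
         call. = FALSE)
  if (sample$unit != blank$unit)
    stop("sample (", sample$unit, ") and blank (", blank$unit,
         ") heat units differ", call. = FALSE)
  itc_series(sample$heats - blank$heats, sample$volumes_uL, sample$unit)
}

# Fit a single one-site ITC series (heats already uJ, blank-corrected).
.fit_itc1_one <- function(y_all, design, chelator, control, exclude_first) {
  use <- seq_along(y_all)
  if (exclude_first && length(use) > 1) use <- use[-1]
  y <- y_all[use]
  if (length(y) < 6)
    stop("need at least 6 usable injections for a one-site ITC fit",
         call. = FALSE)

  basis <- function(logK) {
    st <- .itc_states(design, peptide_model(1, 10 ^ logK), chelator)
    .dn_uJ_per_kJ(st$MP, design$V0_uL)[use]
  }
  resid_fn <- function(logK) {
    a <- tryCatch(basis(logK), error = function(e) NULL)
    if (is.null(a)) return(rep(1e6, length(y)))
    dH <- sum(a * y) / max(sum(a * a), 1e-300)
    y - dH * a
  }
  g <- seq(control$start_range[1], control$start_range[2],
           length.out = control$n_starts)
  best <- .profiled_fit(y, resid_fn, cbind(g), control)
  logK <- unname(best$par[1])
  a <- basis(logK)
  dH <- sum(a * y) / max(sum(a * a), 1e-300)
  fitted <- dH * a
  rss <- sum((y - fitted)^2)

  est <- c(log10_K = logK, dH = dH)
  pred_fn <- function(theta) theta[2] * basis(theta[1])
  J <- .num_jac(pred_fn, est)
  seinfo <- .se_from_jac(J, rss, length(y), 2)

  # saturation diagnostic: occupancy range actually probed by the titration
  st <- .itc_states(design, peptide_model(1, 10 ^ logK), chelator)
  occ <- with(st[-1, ], ifelse(peptide > 0, MP / peptide, 0))
  # a titration that never leaves (or never reaches) saturation carries
  # little information about K: flag it rather than report a sharp estimate
  low_info <- diff(range(occ)) < 0.2 || min(occ) > 0.95
  list(estimates = est, se = stats::setNames(seinfo$se, names(est)),
       rss = rss, fitted = fitted, residuals = y - fitted,
       used = use, n = length(y),
       covariance_singular = seinfo$singular,
       unidentifiable = seinfo$singular || abs(dH) < 1e-8 || low_info,
       occupancy_range = range(occ))
}

#' Fit a one-site ITC titration
#'
#' Least squares on blank-corrected injection heats via
#' [predict_heats_one_site()]. K is parameterized as log10 K with a
#' deterministic multi-start grid; dH enters linearly and is profiled out.
#' The first injection is excluded from the fit by default.
#'
#' @param series An [itc_series()] or list of replicate series.
#' @param design The [itc_design()].
#' @param chelator A [chelator_model()] or `NULL`.
#' @param blank Optional matched blank [itc_series()] (or list), subtracted
#'   before fitting.
#' @param control A [fit_control()] list.
#' @param exclude_first Drop the first injection from the residuals.
#' @return An object of class `"itc_fit"` with per-replicate fits and a
#'   summary (`K`, `dH`); the `unidentifiable` flag marks degenerate fits
#'   (e.g. all-zero heats or saturation regimes carrying no information
#'   about K).
#' @export
fit_itc_one_site <- function(series, design, chelator = NULL, blank = NULL,
                             control = fit_control(),
                             exclude_first = TRUE) {
  if (inherits(series, "itc_series")) series <- list(series)
  if (inherits(blank, "itc_series")) blank <- list(blank)
  if (!is.null(blank))
    series <- mapply(subtract_blank, series, blank, SIMPLIFY = FALSE)
  fits <- lapply(series, function(s)
    .fit_itc1_one(.heats_uJ(s), design, chelator, control, exclude_first))
  summ <- .summarize_replicates(fits, transform_K = TRUE)
  structure(list(kind = "one-site", fits = fits, summary = summ,
                 n_replicates = length(series),
                 unidentifiable = any(vapply(fits, `[[`, logical(1),
                                             "unidentifiable"))),
            class = "itc_fit")
}

# Fit a single two-site ITC series with (KII, dH_II) fixed.
.fit_itc2_one <- function(y_all, design, chelator, fixed, control,
                          exclude_first) {
  use <- seq_along(y_all)
  if (exclude_first && length(use) > 1) use <- use[-1]
  y <- y_all[use]
  if (length(y) < 8)
    stop("need at least 8 usable injections for a two-site ITC fit",
         call. = FALSE)
  KII <- fixed$KII; dH_II <- fixed$dH_II

  cols <- function(p) {  # p = c(log10_KI, log10_K2)
    KI <- 10 ^ p[1]; K2 <- 10 ^ p[2]
    st <- .itc_states(design, peptide_model(2, KI + KII, K2), chelator)
    fI <- KI / (KI + KII)
    dn_I <- .dn_uJ_per_kJ(st$MP * fI, design$V0_uL)[use]
    dn_II <- .dn_uJ_per_kJ(st$MP * (1 - fI), design$V0_uL)[use]
    dn_2 <- .dn_uJ_per_kJ(st$M2P, design$V0_uL)[use]
    cbind(c1 = dn_I + dn_2, c2 = dn_II + dn_2, c3 = dn_2)
  }
  lin_solve <- function(cc) {
    yy <- y - dH_II * cc[, "c2"]
    B <- cc[, c("c1", "c3")]
    b <- qr.coef(qr(B), yy)
    b[is.na(b)] <- 0
    list(dH_I = unname(b[1]), dH_c = unname(b[2]),
         fitted = dH_II * cc[, "c2"] + as.vector(B %*% b))
  }
  resid_fn <- function(p) {
    cc <- tryCatch(cols(p), error = function(e) NULL)
    if (is.null(cc)) return(rep(1e6, length(y)))
    y - lin_solve(cc)$fitted
  }
  g <- seq(control$start_range[1], control$start_range[2],
           length.out = control$n_starts)
  best <- .profiled_fit(y, resid_fn, cbind(g, pmax(g - 0.85, 3)), control)
  p <- best$par
  cc <- cols(p)
  lin <- lin_solve(cc)
  fitted <- lin$fitted
  rss <- sum((y - fitted)^2)

  est <- c(log10_KI = unname(p[1]), dH_I = lin$dH_I,
           log10_K2 = unname(p[2]), dH_c = lin$dH_c)
  pred_fn <- function(theta) {
    cc <- cols(c(theta[["log10_KI"]], theta[["log10_K2"]]))
    theta[["dH_I"]] * cc[, "c1"] + dH_II * cc[, "c2"] +
      theta[["dH_c"]] * cc[, "c3"]
  }
  J <- .num_jac(pred_fn, est)
  seinfo <- .se_from_jac(J, rss, length(y), length(est))
  corKIK2 <- tryCatch({
    cv <- solve(crossprod(J))
    cv[1, 3] / sqrt(cv[1, 1] * cv[3, 3])
  }, error = function(e) NA_real_)

  list(estimates = est, se = stats::setNames(seinfo$se, names(est)),
       rss = rss, fitted = fitted, residuals = y - fitted,
       used = use, n = length(y),
       covariance_singular = seinfo$singular,
       cor_KI_K2 = corKIK2)
}

#' Fit a two-site cooperative ITC titration with site II fixed
#'
#' Fits `(KI, dH_I, K2, dH_c)` by least squares through
#' [predict_heats_two_site()], with the site II parameters `(KII, dH_II)`
#' fixed to values obtained from the corresponding one-site variant. The
#' macroscopic constant `K1 = KI + KII` and the full microscopic set,
#' cooperativity free energy and entropy terms are derived from the
#' estimates (recomputed, never stored independently).
#'
#' @param series An [itc_series()] or list of replicate series.
#' @param design The [itc_design()].
#' @param chelator A [chelator_model()] or `NULL`.
#' @param fixed A list with `KII` (1/M) and `dH_II` (kJ/mol).
#' @param blank Optional matched blank series (or list).
#' @param control A [fit_control()] list.
#' @param exclude_first Drop the first injection from the residuals.
#' @param sensitivity If `TRUE`, refit with `(KII, dH_II)` perturbed by +10%
#'   and report the induced shifts in the estimates.
#' @return An object of class `"itc_fit"` with per-replicate fits, a summary
#'   over `KI`, `dH_I`, `K2`, `dH_c`, the echoed fixed values and a
#'   `derive()`-style block (`K1`, microscopic constants, `ddG`, `Kc`,
#'   entropy terms) computed from the mean estimates.
#' @export
fit_itc_two_site <- function(series, design, chelator = NULL, fixed,
                             blank = NULL, control = fit_control(),
                             exclude_first = TRUE, sensitivity = FALSE) {
  stopifnot(is.list(fixed), all(c("KII", "dH_II") %in% names(fixed)),
            fixed$KII > 0)
  if (inherits(series, "itc_series")) series <- list(series)
  if (inherits(blank, "itc_series")) blank <- list(blank)
  if (!is.null(blank))
    series <- mapply(subtract_blank, series, blank, SIMPLIFY = FALSE)
  fits <- lapply(series, function(s)
    .fit_itc2_one(.heats_uJ(s), design, chelator, fixed, control,
                  exclude_first))
  summ <- .summarize_replicates(fits, transform_K = TRUE)

  KI <- summ$mean[summ$parameter == "KI"]
  K2 <- summ$mean[summ$parameter == "K2"]
  dH_I <- summ$mean[summ$parameter == "dH_I"]
  dH_c <- summ$mean[summ$parameter == "dH_c"]
  cond <- conditions(design$temperature, pH = design$pH)
  micro <- micro_from_macro(macro_constants(KI + fixed$KII, K2),
                            KII = fixed$KII)
  coop <- cooperativity(micro, cond)
  derived <- list(
    K1 = KI + fixed$KII, micro = micro, ddG = coop$ddG, Kc = coop$Kc,
    TdS_I = entropy_term(micro$KI, dH_I, cond),
    TdS_II = entropy_term(micro$KII, fixed$dH_II, cond),
    TdS_c = entropy_term(coop$Kc, dH_c, cond))

  sens <- NULL
  if (sensitivity) {
    pert <- list(KII = fixed$KII * 1.1, dH_II = fixed$dH_II * 1.1)
    fits_p <- lapply(series, function(s)
      .fit_itc2_one(.heats_uJ(s), design, chelator, pert, control,
                    exclude_first))
    summ_p <- .summarize_replicates(fits_p, transform_K = TRUE)
    sens <- merge(summ[c("parameter", "mean")],
                  summ_p[c("parameter", "mean")],
                  by = "parameter", suffixes = c("", "_perturbed"))
    sens$shift <- sens$mean_perturbed - sens$mean
  }

  structure(list(kind = "two-site", fits = fits, summary = summ,
                 fixed = fixed, derived = derived, sensitivity = sens,
                 n_replicates = length(series)),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("ITC fit (", x$kind, ", ", x$n_replicates, " replicate(s))\n", sep = "")
  s <- x$summary
  s$mean <- signif(s$mean, 4); s$sd <- signif(s$sd, 3)
  print(s, row.names = FALSE)
  if (!is.null(x$fixed))
    cat(sprintf("fixed: KII = %.3g 1/M, dH_II = %.3g kJ/mol\n",
                x$fixed$KII, x$fixed$dH_II))
  if (!is.null(x$derived))
    cat(sprintf("derived: K1 = %.3g 1/M, ddG = %.3g kJ/mol, Kc = %.3g\n",
                x$derived$K1, x$derived$ddG, x$derived$Kc))
  if (isTRUE(x$unidentifiable))
    cat("warning: fit flagged unidentifiable\n")
  invisible(x)
}
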