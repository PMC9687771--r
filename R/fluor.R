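# Fluorescence competition titrations: forward model and fitting.
#
# The observable is the quenching (or enhancement) of a single aromatic
# reporter upon metal binding. Per mole of peptide the response follows the
# binding polynomial in the free metal concentration [M]; [M] itself comes
# from the full speciation (metal + chelator + peptide) at each titration
# point, so competition with the chelator is modeled explicitly.

#' Fluorescence titration series
#'
#' @param metal_total Cumulative total metal concentration at each point
#'   (mol/L, after any dilution accounting), non-decreasing; the first point
#'   must be the metal-free baseline (0).
#' @param intensity Fluorescence intensity at each point (arbitrary units).
#' @param design A list with elements `C_P` (initial peptide concentration,
#'   mol/L), `C_L` (initial chelator concentration, mol/L), `pH`,
#'   `temperature` (K), optionally `wavelength_nm` and `V0_uL` (initial
#'   volume, required when per-step volumes are supplied).
#' @param added_volume_uL Optional per-step added titrant volumes (uL, same
#'   length as `metal_total`, first entry 0); when present, peptide and
#'   chelator totals are diluted accordingly at each point.
#' @return An object of class `"fluor_series"`.
#' @export
fluor_series <- function(metal_total, intensity, design,
                         added_volume_uL = NULL) {
  stopifnot(length(metal_total) == length(intensity))
  if (is.unsorted(metal_total))
    stop("metal totals must be non-decreasing along the series",
         call. = FALSE)
  need <- c("C_P", "C_L", "pH", "temperature")
  if (!all(need %in% names(design)))
    stop("design must provide ", paste(need, collapse = ", "), call. = FALSE)
  if (!is.null(added_volume_uL)) {
    stopifnot(length(added_volume_uL) == length(metal_total))
    if (is.null(design$V0_uL))
      stop("per-step volumes require design$V0_uL", call. = FALSE)
  }
  structure(list(metal_total = as.numeric(metal_total),
                 intensity = as.numeric(intensity),
                 design = design, added_volume_uL = added_volume_uL),
            class = "fluor_series")
}

#' Baseline-subtracted fluorescence responses
#'
#' `dF_i = F_0 - F_i`, positive for quenching; the first point must be the
#' metal-free baseline.
#'
#' @param series A [fluor_series()].
#' @return Numeric vector of the same length, first element 0.
#' @export
delta_F <- function(series) {
  stopifnot(inherits(series, "fluor_series"))
  if (series$metal_total[1] != 0)
    stop("first point must be the metal-free baseline (metal total 0)",
         call. = FALSE)
  series$intensity[1] - series$intensity
}

#' One-site binding isotherm (per mole of peptide)
#'
#' `dF/C_P = amp * K1 [M] / (1 + K1 [M])`.
#'
#' @param free_M Free metal concentration(s), mol/L.
#' @param K1 Association constant (1/M).
#' @param amp Signal amplitude per mol/L of peptide (signed; quenching
#'   positive under the `F0 - F` convention).
#' @return Response per mol/L of peptide (vectorized).
#' @export
response_one_site <- function(free_M, K1, amp) {
  stopifnot(all(free_M >= 0), K1 > 0)
  x <- K1 * free_M
  amp * x / (1 + x)
}

#' Two-site binding isotherm (per mole of peptide)
#'
#' `dF/C_P = (amp1 K1 [M] + amp2 K1 K2 [M]^2) / (1 + K1 [M] + K1 K2 [M]^2)`.
#' Reduces to [response_one_site()] as `K2 -> 0` and saturates at `amp2`.
#'
#' @param free_M Free metal concentration(s), mol/L.
#' @param K1,K2 Stepwise macroscopic association constants (1/M); `K2 >= 0`.
#' @param amp1,amp2 Amplitudes of the mono- and di-nuclear complexes (signed,
#'   per mol/L of peptide).
#' @return Response per mol/L of peptide (vectorized).
#' @export
response_two_site <- function(free_M, K1, K2, amp1, amp2) {
  stopifnot(all(free_M >= 0), K1 > 0, K2 >= 0)
  x1 <- K1 * free_M
  x2 <- K1 * K2 * free_M^2
  (amp1 * x1 + amp2 * x2) / (1 + x1 + x2)
}

# Per-point component totals with optional dilution accounting.
.fluor_point_totals <- function(series) {
  n <- length(series$metal_total)
  d <- series$design
  if (!is.null(series$added_volume_uL)) {
    dil <- d$V0_uL / (d$V0_uL + cumsum(series$added_volume_uL))
  } else {
    dil <- rep(1, n)
  }
  data.frame(C_M = series$metal_total, C_L = d$C_L * dil, C_P = d$C_P * dil)
}

# Free metal at every titration point for given macroscopic constants.
# Warm-starts each point from the previous solution. Errors carry the index.
.free_metal_series <- function(tot, pH, temperature, chelator, peptide) {
  conc <- .speciation_series(cbind(tot$C_M, tot$C_L, tot$C_P), pH,
                             chelator, peptide)
  conc[, "M"]
}

#' Predict a fluorescence titration curve
#'
#' Forward model: at each point, the free metal concentration is obtained
#' from [solve_speciation()] with the peptide constants of `params`, then the
#' binding isotherm gives the response, scaled by the (possibly diluted)
#' peptide concentration.
#'
#' @param params A list with `kind` (`"one-site"` or `"two-site"`), `K1`,
#'   `amp1` and, for two sites, `K2`, `amp2`.
#' @param series A [fluor_series()] (intensities may be dummy values when
#'   only the design is of interest).
#' @param chelator A [chelator_model()] or `NULL`.
#' @return Numeric vector of predicted `dF` values, and the free-metal series
#'   as attribute `"free_M"`.
#' @export
predict_fluor <- function(params, series, chelator = NULL) {
  stopifnot(inherits(series, "fluor_series"))
  kind <- match.arg(params$kind, c("one-site", "two-site"))
  pep <- if (kind == "one-site") peptide_model(1, params$K1)
         else peptide_model(2, params$K1, params$K2)
  tot <- .fluor_point_totals(series)
  d <- series$design
  m <- .free_metal_series(tot, d$pH, d$temperature, chelator, pep)
  resp <- if (kind == "one-site")
    response_one_site(m, params$K1, params$amp1)
  else
    response_two_site(m, params$K1, params$K2, params$amp1, params$amp2)
  structure(resp * tot$C_P, free_M = m)
}

#' Fitting options for the titration fitters
#'
#' @param n_starts Number of multi-start points for the log10 K grid (>= 5
#'   recommended); starts span `start_range`.
#' @param start_range Range of log10 K covered by the starts.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param max_iter Maximum LM iterations per start.
#' @param pooled Also fit all replicates simultaneously (shared parameters).
#' @param assume_no_dilution Silence the warning emitted when a series has no
#'   per-step volumes (dilution then assumed negligible).
#' @param check_nested For two-site fluorescence fits, also fit the nested
#'   one-site model and run an F-ratio check (skipped in bulk recovery
#'   studies).
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(n_starts = 5, start_range = c(3, 13), ftol = 1e-12,
                        ptol = 1e-10, max_iter = 200, pooled = FALSE,
                        assume_no_dilution = FALSE, check_nested = TRUE) {
  structure(list(n_starts = max(1L, as.integer(n_starts)),
                 start_range = start_range, ftol = ftol, ptol = ptol,
                 max_iter = as.integer(max_iter), pooled = pooled,
                 assume_no_dilution = assume_no_dilution,
                 check_nested = check_nested),
            class = "fit_control")
}

# Profiled residual machinery: amplitudes enter linearly and are solved by
# linear least squares at each trial value of the log10 constants
# (variable projection).
.fluor_basis <- function(logK, kind, series, chelator) {
  tot <- .fluor_point_totals(series)
  d <- series$design
  K1 <- 10 ^ logK[1]
  if (kind == "one-site") {
    pep <- peptide_model(1, K1)
    m <- .free_metal_series(tot, d$pH, d$temperature, chelator, pep)
    B <- cbind(tot$C_P * K1 * m / (1 + K1 * m))
  } else {
    K2 <- 10 ^ logK[2]
    pep <- peptide_model(2, K1, K2)
    m <- .free_metal_series(tot, d$pH, d$temperature, chelator, pep)
    den <- 1 + K1 * m + K1 * K2 * m^2
    B <- cbind(tot$C_P * K1 * m / den, tot$C_P * K1 * K2 * m^2 / den)
  }
  list(B = B, free_M = m)
}

.profiled_fit <- function(y, resid_fn, starts, control) {
  # log10 K is box-constrained to the multi-start range: values outside it
  # are either unphysical or unidentifiable from titration data
  lo <- rep(control$start_range[1], ncol(starts))
  hi <- rep(control$start_range[2], ncol(starts))
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    p0 <- starts[i, ]
    out <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           ftol = control$ftol, ptol = control$ptol,
                           maxiter = control$max_iter)),
      error = function(e) NULL)
    if (is.null(out)) return(list(rss = Inf, par = p0, info = -1L))
    list(rss = out$deviance, par = out$par, info = out$info)
  })
  rss <- vapply(runs, `[[`, numeric(1), "rss")
  # best of the multi-start sweep; ties broken by the lowest log10 K1
  ord <- order(rss, vapply(runs, function(r) r$par[1], numeric(1)))
  runs[[ord[1]]]
}

# Numeric jacobian of a prediction function at a point (central differences).
.num_jac <- function(fn, theta, h = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(NA_real_, length(f0), length(theta))
  for (j in seq_along(theta)) {
    hj <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    J[, j] <- (fn(tp) - fn(tm)) / (2 * hj)
  }
  J
}

.se_from_jac <- function(J, rss, n, p) {
  dof <- max(n - p, 1)
  s2 <- rss / dof
  # column scaling guards against the very different natural scales of
  # log10 K and amplitude/enthalpy parameters
  d <- sqrt(colSums(J^2))
  d[d == 0] <- 1
  JtJ <- crossprod(sweep(J, 2, d, "/"))
  inv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(inv)) return(list(se = rep(NA_real_, p), singular = TRUE))
  cov <- s2 * sweep(sweep(inv, 1, d, "/"), 2, d, "/")
  list(se = sqrt(pmax(diag(cov), 0)), singular = FALSE)
}

# Fit a single fluorescence series; returns estimates on the natural scale.
.fit_fluor_one <- function(series, kind, chelator, control) {
  y <- delta_F(series)
  n_min <- if (kind == "one-site") 4L else 6L
  if (length(y) < n_min)
    stop("need at least ", n_min, " points for a ", kind, " fit",
         call. = FALSE)

  resid_fn <- function(logK) {
    bas <- tryCatch(.fluor_basis(logK, kind, series, chelator),
                    error = function(e) NULL)
    if (is.null(bas)) return(rep(1e6, length(y)))
    amp <- qr.coef(qr(bas$B), y)
    amp[is.na(amp)] <- 0
    y - as.vector(bas$B %*% amp)
  }
  g <- seq(control$start_range[1], control$start_range[2],
           length.out = control$n_starts)
  starts <- if (kind == "one-site") cbind(g) else cbind(g, pmax(g - 0.7, 3))
  best <- .profiled_fit(y, resid_fn, starts, control)

  logK <- best$par
  bas <- .fluor_basis(logK, kind, series, chelator)
  amp <- qr.coef(qr(bas$B), y); amp[is.na(amp)] <- 0
  fitted <- as.vector(bas$B %*% amp)
  rss <- sum((y - fitted)^2)

  if (kind == "one-site") {
    est <- c(log10_K1 = unname(logK[1]), amp1 = unname(amp[1]))
  } else {
    est <- c(log10_K1 = unname(logK[1]), log10_K2 = unname(logK[2]),
             amp1 = unname(amp[1]), amp2 = unname(amp[2]))
  }
  pred_fn <- function(theta) {
    nk <- if (kind == "one-site") 1 else 2
    b <- .fluor_basis(theta[seq_len(nk)], kind, series, chelator)$B
    as.vector(b %*% theta[-seq_len(nk)])
  }
  J <- .num_jac(pred_fn, est)
  seinfo <- .se_from_jac(J, rss, length(y), length(est))
  se <- stats::setNames(seinfo$se, names(est))

  list(estimates = est, se = se, rss = rss, fitted = fitted, residuals = y - fitted,
       free_M = bas$free_M, n = length(y), lm_info = best$info,
       covariance_singular = seinfo$singular)
}

#' Fit fluorescence competition titrations
#'
#' Least-squares fit of the one-site or two-site binding isotherm to one or
#' more replicate series, with the free metal concentration recomputed from
#' the full speciation at every trial parameter value. Association constants
#' are parameterized as log10 values; amplitudes enter linearly and are
#' profiled out. A fixed multi-start grid over log10 K makes the fit
#' deterministic; the best start is selected by residual sum of squares (ties
#' broken by the lower log10 K1).
#'
#' Each replicate is fitted independently; with two or more replicates the
#' summary reports mean and sample standard deviation across replicates,
#' otherwise the standard error from the covariance approximation is used
#' (flagged in the result). When two-site is requested, a nested one-site fit
#' is also run and an F-ratio check records in the diagnostics whether the
#' simpler model would suffice.
#'
#' @param replicates A [fluor_series()] or a list of them.
#' @param kind `"one-site"` or `"two-site"`.
#' @param chelator A [chelator_model()] or `NULL`.
#' @param control A [fit_control()] list.
#' @return An object of class `"fluor_fit"`: per-replicate fits, a parameter
#'   summary table (natural scale: `K1`, `K2`, `amp1`, `amp2`), and
#'   diagnostics.
#' @export
fit_fluor <- function(replicates, kind = c("one-site", "two-site"),
                      chelator = NULL, control = fit_control()) {
  kind <- match.arg(kind)
  if (inherits(replicates, "fluor_series")) replicates <- list(replicates)
  stopifnot(length(replicates) >= 1,
            all(vapply(replicates, inherits, logical(1), "fluor_series")))
  if (!control$assume_no_dilution &&
      any(vapply(replicates, function(s) is.null(s$added_volume_uL),
                 logical(1))))
    warning("no per-step volumes supplied for at least one replicate; ",
            "dilution during the titration is assumed negligible",
            call. = FALSE)

  fits <- lapply(replicates, .fit_fluor_one, kind = kind,
                 chelator = chelator, control = control)

  diagnostics <- list()
  if (kind == "two-site" && isTRUE(control$check_nested)) {
    fits1 <- lapply(replicates, .fit_fluor_one, kind = "one-site",
                    chelator = chelator, control = control)
    # F-ratio for the nested one-site model, per replicate
    fratio <- mapply(function(f2, f1) {
      df2 <- f2$n - 4
      if (df2 <= 0 || f2$rss <= 0) return(NA_real_)
      ((f1$rss - f2$rss) / 2) / (f2$rss / df2)
    }, fits, fits1)
    pval <- stats::pf(fratio, 2, vapply(fits, function(f) f$n - 4, numeric(1)),
                      lower.tail = FALSE)
    diagnostics$f_test_one_vs_two <- data.frame(F = fratio, p = pval)
    diagnostics$one_site_may_suffice <- any(!is.na(pval) & pval > 0.05)
    if (isTRUE(diagnostics$one_site_may_suffice))
      warning("two-site fit not supported by an F-ratio check against the ",
              "nested one-site model for at least one replicate",
              call. = FALSE)
  }

  summ <- .summarize_replicates(fits, transform_K = TRUE)
  pooled <- NULL
  if (control$pooled && length(replicates) > 1) {
    pooled_series <- .concat_fluor(replicates)
    pooled <- .fit_fluor_one(pooled_series, kind, chelator, control)
  }
  structure(list(kind = kind, fits = fits, summary = summ,
                 diagnostics = diagnostics, pooled = pooled,
                 n_replicates = length(replicates)),
            class = "fluor_fit")
}

# Replicate summary: mean +/- sample SD per parameter. Equilibrium constants
# are averaged on the log10 scale (geometric mean, the convention for
# constants, whose fit errors are close to log-normal); their dispersion is
# the sample SD of the replicate constants on the natural scale.
.summarize_replicates <- function(fits, transform_K = FALSE) {
  est <- do.call(rbind, lapply(fits, function(f) f$estimates))
  se <- do.call(rbind, lapply(fits, function(f) f$se))
  nrep <- nrow(est)
  centre <- colMeans(est)
  spread <- if (nrep >= 2) apply(est, 2, stats::sd) else colMeans(se)
  if (transform_K) {
    for (nm in grep("^log10_K", colnames(est), value = TRUE)) {
      knm <- sub("log10_", "", nm)
      kvals <- 10 ^ est[, nm]
      centre <- c(centre, stats::setNames(10 ^ mean(est[, nm]), knm))
      spread <- c(spread, stats::setNames(
        if (nrep >= 2) stats::sd(kvals)
        else log(10) * kvals[1] * se[1, nm], knm))
    }
  }
  data.frame(parameter = names(centre),
             mean = unname(centre),
             sd = unname(spread),
             sd_source = if (nrep >= 2) "replicates" else "covariance",
             n = nrep, row.names = NULL)
}

.concat_fluor <- function(replicates) {
  # Pooled simultaneous fit treats the concatenated points as one series with
  # shared parameters; points are re-sorted by metal total.
  mt <- unlist(lapply(replicates, `[[`, "metal_total"))
  it <- unlist(lapply(replicates, `[[`, "intensity"))
  o <- order(mt)
  fluor_series(mt[o], it[o], replicates[[1]]$design,
               added_volume_uL = NULL)
}

#' @export
print.fluor_fit <- function(x, ...) {
  cat("Fluorescence titration fit (", x$kind, ", ", x$n_replicates,
      " replicate(s))\n", sep = "")
  s <- x$summary
  s$mean <- signif(s$mean, 4); s$sd <- signif(s$sd, 3)
  print(s, row.names = FALSE)
  if (isTRUE(x$diagnostics$one_site_may_suffice))
    cat("note: F-ratio check suggests a one-site model may suffice\n")
  invisible(x)
}
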