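# Chemical speciation at fixed pH: metal + competing chelator + peptide.
#
# All equilibria are expressed with conditional formation constants valid at
# the stated pH and medium; ligand protonation is absorbed into a side-reaction
# coefficient and the proton balance is never solved explicitly.

#' Component totals for a speciation problem
#'
#' Bundles the analytical (total) concentrations of the three components of a
#' competition titration -- metal, chelator and peptide -- together with the
#' solution conditions.
#'
#' @param metal,chelator,peptide Total concentrations (mol/L), each >= 0.
#' @param pH Solution pH (0 < pH < 14). Used to reduce chelator formation
#'   constants to conditional constants; the proton balance itself is not
#'   solved.
#' @param temperature Absolute temperature (K).
#' @return An object of class `"component_totals"`.
#' @examples
#' component_totals(metal = 1e-5, chelator = 5e-4, peptide = 1e-5, pH = 6)
#' @export
component_totals <- function(metal = 0, chelator = 0, peptide = 0,
                             pH = 6, temperature = 298) {
  stopifnot(length(metal) == 1, length(chelator) == 1, length(peptide) == 1)
  if (any(c(metal, chelator, peptide) < 0) || anyNA(c(metal, chelator, peptide)))
    stop("component totals must be non-negative and finite", call. = FALSE)
  if (!is.finite(pH) || pH <= 0 || pH >= 14)
    stop("pH must lie strictly between 0 and 14", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)", call. = FALSE)
  structure(list(metal = metal, chelator = chelator, peptide = peptide,
                 pH = pH, temperature = temperature),
            class = "component_totals")
}

#' Chelator (competing ligand) model
#'
#' Describes a polyprotic chelator by its stepwise acid-dissociation exponents
#' and the metal complexes it forms. Formation constants are cumulative
#' constants beta referenced to the fully deprotonated ligand and the free
#' metal, at the stated temperature and ionic strength; they are reduced to
#' conditional constants at run time via [side_reaction_coefficient()].
#'
#' @param pKa Numeric vector of stepwise pKa values, ordered highest first
#'   (the order in which the fully deprotonated ligand picks up protons).
#' @param species A `data.frame` with columns `m` (metal stoichiometry,
#'   integer >= 1), `l` (ligand stoichiometry, integer >= 1) and `log10_beta`
#'   (cumulative formation-constant exponent).
#' @return An object of class `"chelator_model"`.
#' @seealso [ida_default()] for the iminodiacetate defaults shipped with the
#'   package.
#' @export
chelator_model <- function(pKa = numeric(),
                           species = data.frame(m = integer(), l = integer(),
                                                log10_beta = numeric())) {
  pKa <- as.numeric(pKa)
  if (length(pKa) && is.unsorted(rev(pKa)))
    stop("pKa values must be ordered highest first", call. = FALSE)
  if (!is.data.frame(species) ||
      !all(c("m", "l", "log10_beta") %in% names(species)))
    stop("species must be a data.frame with columns m, l, log10_beta",
         call. = FALSE)
  if (nrow(species) == 0L)
    stop("a chelator model must declare at least one complex species",
         call. = FALSE)
  if (any(species$m < 1) || any(species$l < 1) ||
      any(species$m != round(species$m)) || any(species$l != round(species$l)))
    stop("stoichiometries m, l must be positive integers", call. = FALSE)
  if (!all(is.finite(species$log10_beta)))
    stop("log10_beta must be finite", call. = FALSE)
  species$m <- as.integer(species$m)
  species$l <- as.integer(species$l)
  structure(list(pKa = pKa, species = species[c("m", "l", "log10_beta")]),
            class = "chelator_model")
}

#' Peptide (protein) binding model
#'
#' Stepwise macroscopic association constants for a one- or two-site peptide:
#' `M + P = MP` (K1) and, for two sites, `M + MP = M2P` (K2).
#'
#' @param n_sites 1 or 2.
#' @param K1 First stepwise macroscopic association constant (1/M), > 0.
#' @param K2 Second stepwise constant (1/M), required when `n_sites = 2`.
#' @return An object of class `"peptide_model"`.
#' @export
peptide_model <- function(n_sites = 1, K1, K2 = NULL) {
  if (!n_sites %in% c(1, 2)) stop("n_sites must be 1 or 2", call. = FALSE)
  if (!is.finite(K1) || K1 <= 0) stop("K1 must be > 0", call. = FALSE)
  if (n_sites == 2) {
    if (is.null(K2) || !is.finite(K2) || K2 <= 0)
      stop("two-site models require K2 > 0", call. = FALSE)
  } else K2 <- NULL
  structure(list(n_sites = as.integer(n_sites), K1 = K1, K2 = K2),
            class = "peptide_model")
}

#' Side-reaction coefficient for ligand protonation
#'
#' Fraction by which protonation reduces the effective free-ligand pool at a
#' given pH: `alpha = 1 + sum_k 10^(sum_{i<=k} pKa_i - k * pH)`, so that the
#' total uncomplexed ligand is `alpha` times the fully deprotonated form.
#'
#' @param pKa Stepwise pKa values ordered highest first (may be empty).
#' @param pH Solution pH in (0, 14).
#' @return A scalar `alpha >= 1`.
#' @examples
#' side_reaction_coefficient(c(9.34, 2.61), pH = 6)
#' @export
side_reaction_coefficient <- function(pKa, pH) {
  pKa <- as.numeric(pKa)
  if (length(pKa) && is.unsorted(rev(pKa)))
    stop("pKa values must be ordered highest first", call. = FALSE)
  if (!is.finite(pH) || pH <= 0 || pH >= 14)
    stop("pH must lie strictly between 0 and 14", call. = FALSE)
  if (!length(pKa)) return(1)
  k <- seq_along(pKa)
  1 + sum(10 ^ (cumsum(pKa) - k * pH))
}

#' Conditional formation constants at fixed pH
#'
#' Reduces the cumulative constants of a chelator model to conditional
#' constants referenced to the total uncomplexed (protonated + deprotonated)
#' ligand pool: a species with ligand stoichiometry `q` gets
#' `log10 beta' = log10 beta - q * log10(alpha)`.
#'
#' @param chelator A [chelator_model()].
#' @param pH Solution pH.
#' @return The species `data.frame` with an extra column `log10_beta_cond`.
#' @export
conditional_constants <- function(chelator, pH) {
  stopifnot(inherits(chelator, "chelator_model"))
  alpha <- side_reaction_coefficient(chelator$pKa, pH)
  sp <- chelator$species
  sp$log10_beta_cond <- sp$log10_beta - sp$l * log10(alpha)
  sp
}

# Species labels fixed for downstream stability: "M<m>L<l>", "MP", "M2P".
.species_label <- function(m, l) sprintf("M%dL%d", m, l)

#' Solver settings for [solve_speciation()]
#'
#' @param tol Convergence threshold on the largest Newton step in log10 units.
#' @param max_iter Iteration cap.
#' @param max_step Per-iteration clip on each log10 step (damping).
#' @param residual_tol Relative mass-balance tolerance a converged state must
#'   satisfy.
#' @return A list of class `"speciation_control"`.
#' @export
speciation_control <- function(tol = 1e-10, max_iter = 200L, max_step = 0.5,
                               residual_tol = 1e-10) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 max_step = max_step, residual_tol = residual_tol),
            class = "speciation_control")
}

# Assemble the full stoichiometric system (components M, L, P) for the given
# models at a given pH. Identity rows for the free components come first.
.full_system <- function(chelator, peptide, pH) {
  S <- diag(3)
  logK <- c(0, 0, 0)
  labels <- c("M", "L", "P")
  if (!is.null(chelator)) {
    sp <- conditional_constants(chelator, pH)
    S <- rbind(S, cbind(sp$m, sp$l, 0))
    logK <- c(logK, sp$log10_beta_cond)
    labels <- c(labels, .species_label(sp$m, sp$l))
  }
  if (!is.null(peptide)) {
    S <- rbind(S, c(1, 0, 1))
    logK <- c(logK, log10(peptide$K1))
    labels <- c(labels, "MP")
    if (peptide$n_sites == 2L) {
      S <- rbind(S, c(2, 0, 1))
      logK <- c(logK, log10(peptide$K1) + log10(peptide$K2))
      labels <- c(labels, "M2P")
    }
  }
  dimnames(S) <- NULL
  list(S = S, logK = logK, labels = labels)
}

# Damped Newton-Raphson core on the active components of one point.
# Tvec3 = c(metal, chelator, peptide) totals; x_prev = warm-start log10 free
# concentrations (length 3, -Inf for absent components).
.spec_core <- function(Tvec3, sys, control, x_prev = NULL) {
  act <- Tvec3 > 0
  nsp <- length(sys$labels)
  if (!any(act))
    return(list(conc = numeric(nsp), x3 = rep(-Inf, 3), conv = TRUE,
                iters = 0L, resid = numeric(0)))
  keep <- rowSums(abs(sys$S[, !act, drop = FALSE])) == 0 &
    rowSums(abs(sys$S[, act, drop = FALSE])) > 0
  S <- sys$S[keep, act, drop = FALSE]
  logK <- sys$logK[keep]
  Tv <- Tvec3[act]
  x <- log10(Tv)
  if (!is.null(x_prev)) {
    xp <- x_prev[act]
    ok <- is.finite(xp)
    x[ok] <- xp[ok]
  }
  ln10 <- log(10)
  k <- length(Tv)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    logC <- pmin(logK + as.vector(S %*% x), 300)
    C <- 10 ^ logC
    f <- as.vector(crossprod(S, C)) - Tv
    J <- ln10 * crossprod(S, S * C)
    delta <- tryCatch(solve(J, -f), error = function(e)
      solve(J + diag(1e-12 * max(diag(J)), k), -f))
    delta <- pmin(pmax(delta, -control$max_step), control$max_step)
    x <- x + delta
    if (max(abs(delta)) < control$tol || iter >= control$max_iter) break
  }
  logC <- pmin(logK + as.vector(S %*% x), 300)
  C <- 10 ^ logC
  resid <- (Tv - as.vector(crossprod(S, C))) / pmax(Tv, 1e-30)
  conc <- numeric(nsp)
  conc[keep] <- C
  x3 <- rep(-Inf, 3)
  x3[act] <- x
  list(conc = conc, x3 = x3, conv = max(abs(resid)) <= control$residual_tol,
       iters = iter, resid = resid)
}

# Solve a whole titration series efficiently: the system is assembled once
# and each point warm-starts from the previous solution. Tmat columns:
# metal, chelator, peptide. Returns a matrix with free component and species
# concentrations, one row per point. Errors carry the failing point index.
.speciation_series <- function(Tmat, pH, chelator, peptide,
                               control = speciation_control()) {
  sys <- .full_system(chelator, peptide, pH)
  n <- nrow(Tmat)
  out <- matrix(0, n, length(sys$labels), dimnames = list(NULL, sys$labels))
  x_prev <- NULL
  for (i in seq_len(n)) {
    res <- .spec_core(c(Tmat[i, 1], Tmat[i, 2], Tmat[i, 3]), sys, control,
                      x_prev)
    if (!res$conv)
      stop("speciation failed at point ", i, " of the series (max |relative ",
           "residual| = ", format(max(abs(res$resid)), digits = 3), ")",
           call. = FALSE)
    out[i, ] <- res$conc
    x_prev <- res$x3
  }
  out
}

#' Solve the mass-balance equations for a competition titration point
#'
#' Computes the equilibrium speciation of a solution containing a metal, an
#' optional competing chelator and an optional one- or two-site peptide at
#' fixed pH, by a damped Newton-Raphson iteration on the component mass
#' balances. Unknown free concentrations are iterated in log10 space (which
#' guarantees positivity) with an analytic Jacobian; each step is clipped to
#' `max_step` log10 units and the iteration stops when the largest step falls
#' below `tol`.
#'
#' @param totals A [component_totals()] object.
#' @param chelator A [chelator_model()] or `NULL`.
#' @param peptide A [peptide_model()] or `NULL`.
#' @param control A [speciation_control()] list.
#' @param start Optional named vector of free concentrations
#'   (`metal`, `chelator`, `peptide`) used as a warm start, e.g. the solution
#'   of the previous titration point.
#' @return An object of class `"speciation_state"`: a list with elements
#'   `free` (named free concentrations, zero components included), `species`
#'   (named complex concentrations, labels `"M<m>L<l>"`, `"MP"`, `"M2P"`),
#'   `converged`, `iterations`, `residuals` (relative mass-balance residuals)
#'   and the input `totals`.
#' @examples
#' pep <- peptide_model(1, K1 = 1e6)
#' solve_speciation(component_totals(metal = 1e-5, peptide = 1e-5), peptide = pep)
#' @export
solve_speciation <- function(totals, chelator = NULL, peptide = NULL,
                             control = speciation_control(), start = NULL) {
  stopifnot(inherits(totals, "component_totals"))
  if (!is.null(chelator)) stopifnot(inherits(chelator, "chelator_model"))
  if (!is.null(peptide)) stopifnot(inherits(peptide, "peptide_model"))

  sys <- .full_system(chelator, peptide, totals$pH)
  Tvec3 <- c(totals$metal, totals$chelator, totals$peptide)
  x_prev <- NULL
  if (!is.null(start)) {
    s0 <- unname(start[c("metal", "chelator", "peptide")])
    x_prev <- ifelse(is.finite(s0) & !is.na(s0) & s0 > 0, log10(s0), -Inf)
  }
  res <- .spec_core(Tvec3, sys, control, x_prev)

  conc <- stats::setNames(res$conc, sys$labels)
  free <- c(metal = unname(conc["M"]), chelator = unname(conc["L"]),
            peptide = unname(conc["P"]))
  free[!is.finite(free)] <- 0
  free[Tvec3 == 0] <- 0
  is_free <- sys$labels %in% c("M", "L", "P")
  species <- conc[!is_free]  # complexes, including exact zeros

  st <- structure(list(free = free, species = species,
                       converged = FALSE, iterations = res$iters,
                       residuals = NULL, totals = totals),
                  class = "speciation_state")
  st$residuals <- mass_balance_residuals(st, totals, chelator, peptide)
  st$converged <- max(abs(st$residuals)) <= control$residual_tol
  if (!st$converged) {
    cond <- structure(
      class = c("speciation_nonconvergence", "error", "condition"),
      list(message = sprintf(
             "speciation did not converge in %d iterations (max |relative residual| = %.3g)",
             iter, max(abs(st$residuals))),
           call = sys.call(-1), state = st))
    stop(cond)
  }
  st
}

#' Relative mass-balance residuals of a speciation state
#'
#' For each component, `(total - reconstructed total) / max(total, floor)`;
#' the floor guards the zero-total case.
#'
#' @param state A `"speciation_state"`.
#' @param totals The [component_totals()] the state was solved for.
#' @param chelator,peptide The models used (needed for stoichiometries).
#' @param floor Denominator floor (mol/L).
#' @return Named numeric vector `c(metal, chelator, peptide)`.
#' @export
mass_balance_residuals <- function(state, totals, chelator = NULL,
                                   peptide = NULL, floor = 1e-30) {
  stopifnot(inherits(state, "speciation_state") | is.list(state))
  rec <- c(metal = unname(state$free["metal"]),
           chelator = unname(state$free["chelator"]),
           peptide = unname(state$free["peptide"]))
  if (length(state$species)) {
    labs <- names(state$species)
    if (!is.null(chelator)) {
      sp <- chelator$species
      for (r in seq_len(nrow(sp))) {
        lab <- .species_label(sp$m[r], sp$l[r])
        if (lab %in% labs) {
          rec["metal"] <- rec["metal"] + sp$m[r] * state$species[[lab]]
          rec["chelator"] <- rec["chelator"] + sp$l[r] * state$species[[lab]]
        }
      }
    }
    if ("MP" %in% labs) {
      rec["metal"] <- rec["metal"] + state$species[["MP"]]
      rec["peptide"] <- rec["peptide"] + state$species[["MP"]]
    }
    if ("M2P" %in% labs) {
      rec["metal"] <- rec["metal"] + 2 * state$species[["M2P"]]
      rec["peptide"] <- rec["peptide"] + state$species[["M2P"]]
    }
  }
  Tvec <- c(metal = totals$metal, chelator = totals$chelator,
            peptide = totals$peptide)
  (Tvec - rec) / pmax(Tvec, floor)
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("Speciation state (pH ", format(x$totals$pH), ", ",
      format(x$totals$temperature), " K)\n", sep = "")
  cat("  converged:", x$converged, "in", x$iterations, "iterations\n")
  cat("  free concentrations (M):\n")
  print(signif(x$free, 6))
  if (length(x$species)) {
    cat("  complexes (M):\n")
    print(signif(x$species, 6))
  }
  invisible(x)
}

#' Default iminodiacetate (IDA) chelator model
#'
#' Loads the IDA configuration shipped with the package: stepwise pKa values
#' and three uranyl-IDA complex species at 25 C, I = 0.1 M. These are
#' synthetic placeholder literature values intended to be replaced by the
#' user's own critically selected constants (see the file
#' `inst/extdata/ida_synthetic_defaults.json`); every computation takes the
#' chelator model as an input and nothing depends on these particular numbers.
#'
#' @return A [chelator_model()].
#' @export
ida_default <- function() {
  path <- system.file("extdata", "ida_synthetic_defaults.json",
                      package = "coopbind")
  read_system_config(path)$chelator
}
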