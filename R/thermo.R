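# Macroscopic <-> microscopic binding-constant algebra for a two-site
# molecule, cooperativity free energy, and enthalpy/entropy decomposition.
#
# Conventions: association constants K in 1/M; energies in kJ/mol;
# R = 8.314 J/(mol K). For a two-site molecule the four site-specific
# (microscopic) constants are KI and KII for binding to the empty molecule,
# and KI_II / KII_I for binding to site I (resp. II) when the other site is
# already occupied. They relate to the stepwise macroscopic constants by
#   K1 = KI + KII,      K1 * K2 = KI * KII_I = KII * KI_II  (detailed balance:
# the two paths to the doubly loaded molecule have equal overall constants).

.R_GAS <- 8.314  # J / (mol K)

#' Experimental conditions for thermodynamic conversions
#'
#' @param temperature Absolute temperature (K); default 298.
#' @param pH,ionic_strength Metadata carried along with results.
#' @return A list of class `"conditions"` with the gas constant fixed at
#'   8.314 J/(mol K).
#' @export
conditions <- function(temperature = 298, pH = NA_real_,
                       ionic_strength = NA_real_) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (kelvin)", call. = FALSE)
  structure(list(temperature = temperature, gas_constant = .R_GAS,
                 pH = pH, ionic_strength = ionic_strength),
            class = "conditions")
}

#' Macroscopic stepwise binding constants
#'
#' @param K1 First stepwise association constant (1/M), > 0.
#' @param K2 Second stepwise constant (1/M), optional.
#' @return A list of class `"macro_constants"`.
#' @export
macro_constants <- function(K1, K2 = NULL) {
  if (!is.finite(K1) || K1 <= 0) stop("K1 must be > 0", call. = FALSE)
  if (!is.null(K2) && (!is.finite(K2) || K2 <= 0))
    stop("K2 must be > 0 when supplied", call. = FALSE)
  structure(list(K1 = K1, K2 = K2), class = "macro_constants")
}

#' Microscopic (site-specific) binding constants
#'
#' Validates positivity and the detailed-balance identity
#' `KI * KII_I = KII * KI_II` (the two paths to the doubly loaded molecule
#' must have equal overall constants, to `tol` relative).
#'
#' @param KI,KII Constants for binding at site I / II of the empty molecule.
#' @param KI_II Constant for site I when site II is occupied.
#' @param KII_I Constant for site II when site I is occupied.
#' @param tol Relative tolerance for the detailed-balance check.
#' @return A list of class `"micro_constants"`.
#' @export
micro_constants <- function(KI, KII, KI_II, KII_I, tol = 1e-9) {
  k <- c(KI = KI, KII = KII, KI_II = KI_II, KII_I = KII_I)
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all microscopic constants must be positive and finite",
         call. = FALSE)
  lhs <- KI * KII_I; rhs <- KII * KI_II
  if (abs(lhs - rhs) > tol * max(lhs, rhs))
    stop("detailed balance violated: KI*KII_I != KII*KI_II (relative error ",
         format(abs(lhs - rhs) / max(lhs, rhs), digits = 3), ")",
         call. = FALSE)
  structure(as.list(k), class = "micro_constants")
}

#' Microscopic constants from macroscopic ones plus an independent KII
#'
#' Given the two stepwise macroscopic constants and an independently measured
#' site II constant (e.g. from a one-site variant of the same protein),
#' derives the full microscopic set:
#' `KI = K1 - KII`, `KI_II = K1*K2/KII`, `KII_I = K1*K2/KI`.
#'
#' @param macro A [macro_constants()] with both K1 and K2.
#' @param KII Site II association constant (1/M), `0 < KII < K1`.
#' @return A [micro_constants()] object satisfying detailed balance by
#'   construction.
#' @examples
#' micro_from_macro(macro_constants(3.5e7, 7.4e6), KII = 3.7e6)
#' @export
micro_from_macro <- function(macro, KII) {
  stopifnot(inherits(macro, "macro_constants"))
  if (is.null(macro$K2))
    stop("micro_from_macro requires both K1 and K2", call. = FALSE)
  if (!is.finite(KII) || KII <= 0)
    stop("KII must be > 0", call. = FALSE)
  if (KII >= macro$K1)
    stop("KII must be smaller than K1: site I constant K1 - KII would be ",
         "non-positive", call. = FALSE)
  KI <- macro$K1 - KII
  micro_constants(KI = KI, KII = KII,
                  KI_II = macro$K1 * macro$K2 / KII,
                  KII_I = macro$K1 * macro$K2 / KI)
}

#' Macroscopic constants from a microscopic set
#'
#' `K1 = KI + KII`; `K2 = KI * KII_I / (KI + KII)`. Exact algebraic inverse
#' of [micro_from_macro()].
#'
#' @param micro A [micro_constants()] object.
#' @return A [macro_constants()] object.
#' @export
macro_from_micro <- function(micro) {
  stopifnot(inherits(micro, "micro_constants"))
  macro_constants(K1 = micro$KI + micro$KII,
                  K2 = micro$KI * micro$KII_I / (micro$KI + micro$KII))
}

#' Inter-site cooperativity from microscopic constants
#'
#' The cooperativity constant `Kc = KII_I / KII` (equal to `KI_II / KI` under
#' detailed balance) and the cooperativity free energy
#' `ddG = -RT ln(Kc)` in kJ/mol. `ddG < 0` indicates positive cooperativity
#' (the second binding event is favored by the first).
#'
#' @param micro A [micro_constants()] object.
#' @param cond A [conditions()] object.
#' @return A list of class `"cooperativity_result"` with `Kc` and `ddG`.
#' @examples
#' m <- micro_from_macro(macro_constants(3.5e7, 7.4e6), KII = 3.7e6)
#' cooperativity(m, conditions(298))   # ddG approximately -2 kJ/mol
#' @export
cooperativity <- function(micro, cond = conditions()) {
  stopifnot(inherits(micro, "micro_constants"), inherits(cond, "conditions"))
  Kc <- micro$KII_I / micro$KII
  RT <- cond$gas_constant * cond$temperature / 1000  # kJ/mol
  structure(list(Kc = Kc, ddG = -RT * log(Kc), temperature = cond$temperature),
            class = "cooperativity_result")
}

#' Gibbs free energy of association
#'
#' `dG = -RT ln(K)` in kJ/mol, computed in log space.
#'
#' @param K Association constant (1/M), > 0.
#' @param cond A [conditions()] object.
#' @return Energy in kJ/mol (vectorized over `K`).
#' @export
gibbs_from_K <- function(K, cond = conditions()) {
  if (any(!is.na(K) & K <= 0)) stop("K must be > 0", call. = FALSE)
  -(cond$gas_constant * cond$temperature / 1000) * log(K)
}

#' Entropic term of a binding step
#'
#' `T dS = RT ln(K) + dH` (kJ/mol), so that `dG = dH - T dS` closes exactly
#' with `dG = -RT ln(K)`.
#'
#' @param K Association (or cooperativity) constant, > 0.
#' @param deltaH Molar enthalpy of the step (kJ/mol).
#' @param cond A [conditions()] object.
#' @return `T dS` in kJ/mol (vectorized).
#' @export
entropy_term <- function(K, deltaH, cond = conditions()) {
  -gibbs_from_K(K, cond) + deltaH
}

#' Free-energy decomposition of a binding step
#'
#' @param K Association constant (1/M).
#' @param deltaH Molar enthalpy (kJ/mol).
#' @param cond A [conditions()] object.
#' @return A list of class `"thermo_decomposition"` with `deltaG`, `deltaH`,
#'   `TdeltaS` (kJ/mol) and `temperature`; `deltaG = deltaH - TdeltaS` holds
#'   by construction.
#' @export
thermo_decomposition <- function(K, deltaH, cond = conditions()) {
  dG <- gibbs_from_K(K, cond)
  structure(list(deltaG = dG, deltaH = deltaH, TdeltaS = deltaH - dG,
                 temperature = cond$temperature),
            class = "thermo_decomposition")
}

#' Dissociation constant with auto-scaled unit
#'
#' `Kd = 1/K`, reported with the SI prefix (M, mM, uM, nM, pM, fM) chosen so
#' the mantissa falls in `[1, 1000)`.
#'
#' @param K Association constant (1/M), > 0.
#' @return A list of class `"kd_value"` with `Kd_M` (value in mol/L), `value`
#'   (scaled mantissa) and `unit`.
#' @examples
#' kd_from_K(5.1e9)   # 196 pM
#' @export
kd_from_K <- function(K) {
  if (!is.finite(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  kd <- 1 / K
  units <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15)
  i <- findInterval(-log10(kd), c(-Inf, 0, 3, 6, 9, 12) + log10(1) + 1e-12)
  i <- min(max(i, 1L), length(units))
  structure(list(Kd_M = kd, value = kd / units[[i]],
                 unit = names(units)[i]),
            class = "kd_value")
}

#' @export
print.kd_value <- function(x, ...) {
  cat(format(signif(x$value, 3)), x$unit, "\n")
  invisible(x)
}

#' @export
print.cooperativity_result <- function(x, ...) {
  cat(sprintf("Cooperativity: Kc = %.4g, ddG = %.3g kJ/mol (%s)\n",
              x$Kc, x$ddG,
              if (x$ddG < 0) "positive" else if (x$ddG > 0) "negative"
              else "none"))
  invisible(x)
}
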