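# Readers and writers: chemical-system configuration (JSON), titration series
# (comma-separated text) and result records. Numeric round-trips are written
# with 17 significant digits so that write -> read is lossless.

.known_config_keys <- c("notes", "chelator", "peptide", "conditions", "fit",
                        "report")

#' Read a chemical-system configuration
#'
#' Parses a JSON configuration with blocks `chelator` (pKa list and complex
#' species), `peptide` (n_sites, K1, K2), `conditions` (pH, T,
#' ionic_strength) and optional `fit`/`report` option blocks. Unknown
#' top-level keys are rejected; a free-form `notes` string is allowed.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `chelator` ([chelator_model()] or `NULL`),
#'   `peptide` ([peptide_model()] or `NULL`), `conditions` (list), and any
#'   `fit`/`report` blocks present.
#' @export
read_system_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- list(chelator = NULL, peptide = NULL,
              conditions = list(pH = 6, T = 298, ionic_strength = NA_real_))
  if (!is.null(cfg$chelator)) {
    ch <- cfg$chelator
    unknown <- setdiff(names(ch), c("pKa", "species"))
    if (length(unknown))
      stop("unknown chelator keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$chelator <- chelator_model(pKa = ch$pKa,
                                   species = as.data.frame(ch$species))
  }
  if (!is.null(cfg$peptide)) {
    pe <- cfg$peptide
    unknown <- setdiff(names(pe), c("n_sites", "K1", "K2"))
    if (length(unknown))
      stop("unknown peptide keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$peptide <- peptide_model(n_sites = pe$n_sites, K1 = pe$K1,
                                 K2 = pe$K2)
  }
  if (!is.null(cfg$conditions)) {
    co <- cfg$conditions
    unknown <- setdiff(names(co), c("pH", "T", "ionic_strength"))
    if (length(unknown))
      stop("unknown conditions keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$conditions <- utils::modifyList(out$conditions, co)
  }
  for (k in c("fit", "report")) if (!is.null(cfg[[k]])) out[[k]] <- cfg[[k]]
  out
}

#' Write a chemical-system configuration
#'
#' Inverse of [read_system_config()]; numeric values keep full precision.
#'
#' @param config A list as returned by [read_system_config()], or with the
#'   same structure.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_system_config <- function(config, path) {
  out <- list()
  if (!is.null(config$chelator))
    out$chelator <- list(pKa = config$chelator$pKa,
                         species = config$chelator$species)
  if (!is.null(config$peptide)) {
    pe <- config$peptide
    out$peptide <- list(n_sites = pe$n_sites, K1 = pe$K1)
    if (!is.null(pe$K2)) out$peptide$K2 <- pe$K2
  }
  out$conditions <- config$conditions
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# full-precision numeric formatting for delimited output
.fmt17 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

.write_delim <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fluorescence titration series
#'
#' Expects comma-separated text with header columns `step`,
#' `added_metal_total_M`, `intensity` and optionally `added_volume_uL`.
#' The first row must be the metal-free baseline.
#'
#' @param path Input file.
#' @param design A list of design metadata (`C_P`, `C_L`, `pH`,
#'   `temperature`, optionally `V0_uL`); attached to the series.
#' @return A `"fluor_series"` object (see [fluor_series()]).
#' @export
read_fluor_series <- function(path, design) {
  df <- utils::read.csv(path)
  need <- c("step", "added_metal_total_M", "intensity")
  if (!all(need %in% names(df)))
    stop("fluorescence series must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  vol <- if ("added_volume_uL" %in% names(df)) df$added_volume_uL else NULL
  fluor_series(metal_total = df$added_metal_total_M,
               intensity = df$intensity, design = design,
               added_volume_uL = vol)
}

#' Write a fluorescence titration series
#'
#' @param series A `"fluor_series"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fluor_series <- function(series, path) {
  df <- data.frame(step = seq_along(series$metal_total) - 1L,
                   added_metal_total_M = series$metal_total,
                   intensity = series$intensity)
  if (!is.null(series$added_volume_uL))
    df$added_volume_uL <- series$added_volume_uL
  .write_delim(df, path)
}

#' Read an ITC injection-heat series
#'
#' Expects comma-separated text with columns `injection`, `volume_uL` and a
#' heat column whose name carries the unit tag: `heat_uJ` or `heat_ucal`.
#'
#' @param path Input file.
#' @return An `"itc_series"` object (see [itc_series()]), heats in uJ.
#' @export
read_itc_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("injection", "volume_uL") %in% names(df)))
    stop("ITC series must have columns injection, volume_uL", call. = FALSE)
  heat_col <- grep("^heat_(uJ|ucal)$", names(df), value = TRUE)
  if (length(heat_col) != 1)
    stop("ITC series must have exactly one heat column named heat_uJ or heat_ucal",
         call. = FALSE)
  unit <- sub("^heat_", "", heat_col)
  itc_series(heats = df[[heat_col]], volumes_uL = df$volume_uL, unit = unit)
}

#' Write an ITC injection-heat series
#'
#' @param series An `"itc_series"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_itc_series <- function(series, path) {
  df <- data.frame(injection = seq_along(series$heats),
                   volume_uL = series$volumes_uL)
  df[[paste0("heat_", series$unit)]] <- series$heats
  .write_delim(df, path)
}

#' Write a speciation state as a delimited table
#'
#' One row per species (free components included), columns
#' `species,concentration_M`.
#'
#' @param state A `"speciation_state"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_speciation <- function(state, path) {
  free <- state$free[state$free > 0 | c(state$totals$metal,
                                        state$totals$chelator,
                                        state$totals$peptide) > 0]
  lab <- c(metal = "M", chelator = "L", peptide = "P")[names(free)]
  df <- data.frame(species = c(unname(lab), names(state$species)),
                   concentration_M = c(unname(free), unname(state$species)))
  .write_delim(df, path)
}
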