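# End-to-end workflow: fit the one-site peptide's ITC to fix (KII, dH_II),
# fit the two-site peptide's ITC, derive microscopic constants, the
# cooperativity free energy and the entropy terms, and assemble a report
# table mirroring the primary/derived-constant tables of a two-site binding
# study.

#' Derive microscopic constants and thermodynamic terms from primary ones
#'
#' For each row of primary constants (macroscopic `K1`, `K2`, an independent
#' site II constant `KII`, and optionally the enthalpies `dH_I`, `dH_II`,
#' `dH_c`), computes the full microscopic set, dissociation constants, the
#' cooperativity free energy and constant, and -- when enthalpies are
#' present -- the entropic terms `TdS_I = RT ln KI + dH_I`,
#' `TdS_II = RT ln KII + dH_II`, `TdS_c = RT ln Kc + dH_c` (all kJ/mol).
#' One-site rows (missing `K2`/`KII`) get `Kd1` and, with `dH_II`, `TdS_II`
#' computed from `K1 = KII`.
#'
#' @param tbl A `data.frame` with columns `peptide`, `pH`, `K1` and
#'   optionally `K2`, `KII`, `dH_I`, `dH_II`, `dH_c` (1/M and kJ/mol).
#' @param temperature Temperature (K) for the thermodynamic conversions.
#' @return The input with derived columns appended: `Kd1_nM`, `Kd2_nM`,
#'   `KI`, `KI_II`, `KII_I`, `ddG`, `Kc`, `TdS_I`, `TdS_II`, `TdS_c`.
#'   Rows whose constants violate `KII < K1` get `NA` derived values and a
#'   note in the `flag` column.
#' @examples
#' derive_table(data.frame(peptide = "CaM Y I-II", pH = 6,
#'                         K1 = 3.5e7, K2 = 7.4e6, KII = 3.7e6))
#' @export
derive_table <- function(tbl, temperature = 298) {
  stopifnot(is.data.frame(tbl), all(c("peptide", "pH", "K1") %in% names(tbl)))
  for (cn in c("K2", "KII", "dH_I", "dH_II", "dH_c"))
    if (is.null(tbl[[cn]])) tbl[[cn]] <- NA_real_
  n <- nrow(tbl)
  out <- tbl
  out$Kd1_nM <- 1e9 / tbl$K1
  out$Kd2_nM <- ifelse(is.na(tbl$K2), NA_real_, 1e9 / tbl$K2)
  out$KI <- out$KI_II <- out$KII_I <- out$ddG <- out$Kc <- NA_real_
  out$TdS_I <- out$TdS_II <- out$TdS_c <- NA_real_
  out$flag <- ""
  cond <- conditions(temperature)
  for (i in seq_len(n)) {
    two_site <- !is.na(tbl$K2[i]) && !is.na(tbl$KII[i])
    if (two_site) {
      if (tbl$KII[i] >= tbl$K1[i]) {
        out$flag[i] <- "KII >= K1: microscopic set undefined"
        next
      }
      micro <- micro_from_macro(macro_constants(tbl$K1[i], tbl$K2[i]),
                                KII = tbl$KII[i])
      coop <- cooperativity(micro, cond)
      out$KI[i] <- micro$KI
      out$KI_II[i] <- micro$KI_II
      out$KII_I[i] <- micro$KII_I
      out$ddG[i] <- coop$ddG
      out$Kc[i] <- coop$Kc
      if (!is.na(tbl$dH_I[i]))
        out$TdS_I[i] <- entropy_term(micro$KI, tbl$dH_I[i], cond)
      if (!is.na(tbl$dH_II[i]))
        out$TdS_II[i] <- entropy_term(micro$KII, tbl$dH_II[i], cond)
      if (!is.na(tbl$dH_c[i]))
        out$TdS_c[i] <- entropy_term(coop$Kc, tbl$dH_c[i], cond)
    } else {
      # one-site peptide: K1 is the site constant itself
      if (!is.na(tbl$dH_II[i]))
        out$TdS_II[i] <- entropy_term(tbl$K1[i], tbl$dH_II[i], cond)
    }
  }
  out
}

#' Run the one-site -> two-site ITC analysis workflow
#'
#' Fixed stage order: (1) fit the one-site peptide's ITC series to obtain
#' `(KII, dH_II)`; (2) fit the two-site peptide's ITC series with those
#' values fixed; (3) derive `K1 = KI + KII`, the microscopic constants, the
#' cooperativity free energy and all entropy terms; (4) assemble a one-row
#' report table. Alternatively, `(KII, dH_II)` may be supplied directly in
#' `two_site$fixed` and the one-site stage skipped.
#'
#' @param config A system configuration as returned by
#'   [read_system_config()] (the `chelator` element is used).
#' @param one_site `NULL`, or a list with `series` (an [itc_series()] or
#'   list of replicates), `design` (an [itc_design()]), optional `blank` and
#'   `label`.
#' @param two_site A list with `series`, `design`, optional `blank`,
#'   `label`, and optional `fixed` (list with `KII`, `dH_II`) used when
#'   `one_site` is `NULL`.
#' @param control A [fit_control()].
#' @param verbose Print per-stage progress.
#' @return A list of class `"workflow_result"` with `one_site_fit`,
#'   `two_site_fit`, `report` (the [derive_table()] row) and `fixed`.
#' @export
run_workflow <- function(config, one_site = NULL, two_site,
                         control = fit_control(), verbose = FALSE) {
  chel <- config$chelator
  say <- function(...) if (verbose) message(...)
  one_fit <- NULL
  if (!is.null(one_site)) {
    say("stage 1/3: one-site ITC fit (", one_site$label %||% "one-site", ")")
    one_fit <- fit_itc_one_site(one_site$series, one_site$design, chel,
                                blank = one_site$blank, control = control)
    s <- one_fit$summary
    fixed <- list(KII = s$mean[s$parameter == "K"],
                  dH_II = s$mean[s$parameter == "dH"])
  } else if (!is.null(two_site$fixed)) {
    fixed <- two_site$fixed
    say("stage 1/3: skipped (fixed KII, dH_II supplied)")
  } else {
    stop("two-site analysis requires either one-site data or fixed ",
         "(KII, dH_II) values", call. = FALSE)
  }

  say("stage 2/3: two-site ITC fit (", two_site$label %||% "two-site", ")")
  two_fit <- fit_itc_two_site(two_site$series, two_site$design, chel,
                              fixed = fixed, blank = two_site$blank,
                              control = control)

  say("stage 3/3: deriving microscopic constants and thermodynamic terms")
  s <- two_fit$summary
  g <- function(p) s$mean[s$parameter == p]
  primary <- data.frame(
    peptide = two_site$label %||% "two-site",
    pH = two_site$design$pH,
    K1 = g("KI") + fixed$KII, K2 = g("K2"), KII = fixed$KII,
    dH_I = g("dH_I"), dH_II = fixed$dH_II, dH_c = g("dH_c"))
  report <- derive_table(primary, temperature = two_site$design$temperature)

  structure(list(one_site_fit = one_fit, two_site_fit = two_fit,
                 fixed = fixed, report = report),
            class = "workflow_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize workflow results to JSON
#'
#' Writes the primary estimates, fixed values and report table at full
#' precision; [report_from_json()] regenerates the identical report from the
#' file (derived columns are recomputed from the stored primary estimates,
#' not read back).
#'
#' @param result A `"workflow_result"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_workflow_json <- function(result, path) {
  s <- result$two_site_fit$summary
  g <- function(p) s$mean[s$parameter == p]
  payload <- list(
    fixed = result$fixed,
    estimates = list(KI = g("KI"), dH_I = g("dH_I"),
                     K2 = g("K2"), dH_c = g("dH_c")),
    primary = as.list(result$report[1, c("peptide", "pH", "K1", "K2", "KII",
                                         "dH_I", "dH_II", "dH_c")]),
    temperature = result$report$temperature %||% 298)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Regenerate a report table from stored JSON results
#'
#' @param path A JSON file written by [write_workflow_json()].
#' @return A [derive_table()] report row.
#' @export
report_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  primary <- as.data.frame(payload$primary)
  derive_table(primary, temperature = payload$temperature %||% 298)
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("Workflow result\n")
  cat(sprintf("  fixed: KII = %.4g 1/M, dH_II = %.4g kJ/mol\n",
              x$fixed$KII, x$fixed$dH_II))
  r <- x$report
  num <- vapply(r, is.numeric, logical(1))
  r[num] <- lapply(r[num], signif, 4)
  print(r, row.names = FALSE)
  invisible(x)
}
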