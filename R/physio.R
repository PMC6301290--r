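# Blood-panel preparation: pH temperature correction, validation,
# hyperkalemia flagging.

#' pH temperature-correction settings
#'
#' Point-of-care analysers measure blood pH at 37 C; values must be
#' corrected to the animal's body temperature (approximated by SST). The
#' species-independent conversion equations used historically are published
#' elsewhere and are not baked in: the default mode is `identity` with a
#' one-time notice, and users supply a linear slope (delta pH per deg C)
#' from the literature when they want the correction applied.
#'
#' @param mode `"identity"` (default) or `"linear"`.
#' @param slope delta pH per deg C, used in linear mode:
#'   `ph_corrected = ph37 + slope * (37 - sst)`.
#' @return an object of class `ph_correction`.
#' @export
ph_correction <- function(mode = c("identity", "linear"), slope = 0) {
  mode <- match.arg(mode)
  if (!is.finite(slope)) stopf("slope must be finite")
  structure(list(mode = mode, slope = slope), class = "ph_correction")
}

#' Correct 37 C blood pH to sea surface temperature
#'
#' @param ph37 measured pH at 37 C (must lie in `[6.0, 8.5]`).
#' @param sst_c sea surface temperature, deg C; required (the correction is
#'   a temperature correction).
#' @param corr a [ph_correction()].
#' @return corrected pH, same length as `ph37`.
#' @examples
#' correct_ph(7.30, 27, ph_correction("linear", slope = 0.01))  # 7.40
#' @export
correct_ph <- function(ph37, sst_c, corr = ph_correction()) {
  ok <- !is.na(ph37)
  if (any(ph37[ok] < 6.0 | ph37[ok] > 8.5)) {
    stopf("ph37 outside plausible range [6.0, 8.5]")
  }
  if (corr$mode == "identity") {
    return(ph37)
  }
  if (length(sst_c) == 1) sst_c <- rep(sst_c, length(ph37))
  if (any(ok & is.na(sst_c))) {
    stopf("missing covariate: sst_c (temperature correction requires SST)")
  }
  ph37 + corr$slope * (37 - sst_c)
}

#' Flag hyperkalemia
#'
#' `TRUE` iff plasma potassium strictly exceeds 7.0 mmol l^-1, the
#' threshold above which muscle tetany and elevated mortality risk have
#' been reported for captured elasmobranchs. Missing potassium yields a
#' missing flag, never `FALSE`.
#'
#' @param panel one-row data frame / list with a `potassium` field
#'   (mmol l^-1), or a bare numeric potassium value.
#' @param threshold_mmol_l flag threshold (default 7.0).
#' @return logical (possibly `NA`).
#' @examples
#' flag_hyperkalemia(8.21)  # TRUE
#' flag_hyperkalemia(7.0)   # FALSE (strict threshold)
#' @export
flag_hyperkalemia <- function(panel, threshold_mmol_l = 7.0) {
  k <- if (is.numeric(panel)) panel else panel[["potassium"]]
  if (is.null(k)) return(NA)
  ifelse(is.na(k), NA, k > threshold_mmol_l)
}

#' Validate a blood panel
#'
#' Errors on physically impossible values (negative concentrations,
#' haematocrit outside 0-100 %, pH outside 6.0-8.5); keeps an all-missing
#' panel with a warning (missingness is preserved, never imputed).
#'
#' @param panel one-row data frame or named list with any of `ph37`,
#'   `lactate`, `glucose`, `haematocrit`, `sodium`, `potassium`,
#'   `chloride`, `calcium`.
#' @param quiet suppress the all-missing warning (used during bulk reads).
#' @return the panel, invisibly, if valid.
#' @export
validate_panel <- function(panel, quiet = FALSE) {
  conc <- c("lactate", "glucose", "sodium", "potassium", "chloride", "calcium")
  for (f in conc) {
    v <- panel[[f]]
    if (!is.null(v) && any(!is.na(v) & v < 0)) {
      stopf("negative %s concentration (%g mmol l^-1)", f, min(v, na.rm = TRUE))
    }
  }
  h <- panel[["haematocrit"]]
  if (!is.null(h) && any(!is.na(h) & (h < 0 | h > 100))) {
    stopf("haematocrit must lie in [0, 100] %%")
  }
  p <- panel[["ph37"]]
  if (!is.null(p) && any(!is.na(p) & (p < 6.0 | p > 8.5))) {
    stopf("ph37 outside plausible range [6.0, 8.5]")
  }
  vals <- unlist(panel[intersect(c("ph37", "haematocrit", conc), names(panel))])
  if (length(vals) && all(is.na(vals)) && !quiet) {
    warnf("panel has no measured endpoints; retained as all-missing")
  }
  invisible(panel)
}
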