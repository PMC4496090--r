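#' Closed-form HOMA indices of insulin resistance and beta-cell function
#'
#' Computes the homeostasis-model-assessment indices from fasting glucose
#' and fasting insulin using the classic closed forms:
#' \deqn{HOMA{\text -}IR = G \times I / 22.5, \qquad
#'       HOMA{\text -}B = 20 \times I / (G - 3.5)\ (\%)}
#' with glucose \eqn{G} in mmol/L and insulin \eqn{I} in uU/mL. Insulin
#' supplied in pmol/L is converted by dividing by `insulin_conversion`
#' (default 6, the convention of the reference calculator). The computer-
#' model (HOMA2) variant has no published closed form; the multiplicative
#' `calibration` factors (default 1) let users rescale these closed-form
#' indices towards HOMA2 output if they have paired values to calibrate on.
#'
#' HOMA-B is undefined at glucose <= 3.5 mmol/L (the denominator changes
#' sign); such records get `NA` with no error so they stay in the cohort.
#'
#' @param glucose Fasting plasma glucose, mmol/L (> 0).
#' @param insulin Fasting insulin, pmol/L (> 0).
#' @param insulin_conversion pmol/L per uU/mL; default 6.
#' @param calibration Named numeric vector `c(ir = 1, b = 1)` of
#'   multiplicative calibration factors.
#' @return A list (vectorised over inputs) with `homa_ir` and `homa_b`
#'   (percent; `NA` where glucose <= 3.5).
#' @export
#' @examples
#' homa_indices(glucose = 4.5, insulin = 6)   # IR = 0.2, B = 20 %
homa_indices <- function(glucose, insulin, insulin_conversion = 6,
                         calibration = c(ir = 1, b = 1)) {
  if (any(!is.na(glucose) & glucose <= 0)) {
    stop("glucose must be positive", call. = FALSE)
  }
  if (any(!is.na(insulin) & insulin <= 0)) {
    stop("insulin must be positive", call. = FALSE)
  }
  if (insulin_conversion <= 0) {
    stop("insulin_conversion must be positive", call. = FALSE)
  }
  ins_u <- insulin / insulin_conversion
  homa_ir <- unname(calibration["ir"]) * glucose * ins_u / 22.5
  homa_b <- ifelse(!is.na(glucose) & glucose > 3.5,
                   unname(calibration["b"]) * 20 * ins_u / (glucose - 3.5),
                   NA_real_)
  list(homa_ir = homa_ir, homa_b = homa_b)
}

#' Log-ratio change between two timepoints
#'
#' `ln(final / baseline)`: 0 means no change, the sign matches the
#' direction of change, and on the natural scale the change corresponds to
#' the ratio final/baseline. Used for outcomes whose sampling distribution
#' is symmetric on the log scale.
#'
#' @param baseline,final Positive measurements.
#' @return `log(final) - log(baseline)` (vectorised).
#' @export
log_change_ratio <- function(baseline, final) {
  if (any(!is.na(baseline) & baseline <= 0) ||
      any(!is.na(final) & final <= 0)) {
    stop("log_change_ratio requires positive values", call. = FALSE)
  }
  log(final) - log(baseline)
}

#' Percent of energy from saturated fat
#'
#' @param satfat_g Saturated fat intake, g/day (>= 0).
#' @param energy Total energy intake per day, in the unit implied by
#'   `energy_unit`.
#' @param fat_energy_density Energy density of fat in kJ/g; default 37
#'   (9 kcal/g).
#' @param energy_unit `"kJ"` (default) or `"kcal"`; kcal input is
#'   converted to kJ with 4.184 kJ/kcal.
#' @return Percent of total energy contributed by saturated fat.
#' @export
#' @examples
#' satfat_pct_energy(30, 9250) # 12 %
satfat_pct_energy <- function(satfat_g, energy, fat_energy_density = 37,
                              energy_unit = c("kJ", "kcal")) {
  energy_unit <- match.arg(energy_unit)
  if (any(!is.na(energy) & energy <= 0)) {
    stop("energy must be positive", call. = FALSE)
  }
  if (any(!is.na(satfat_g) & satfat_g < 0)) {
    stop("satfat_g must be non-negative", call. = FALSE)
  }
  energy_kj <- if (energy_unit == "kcal") energy * 4.184 else energy
  100 * satfat_g * fat_energy_density / energy_kj
}

#' Non-starch polysaccharide from AOAC dietary fibre
#'
#' AOAC total dietary fibre overestimates the non-starch polysaccharide
#' (NSP) fraction; the standard conversion multiplies by 0.75.
#'
#' @param aoac_fibre_g AOAC dietary fibre, g/day (>= 0).
#' @param factor Conversion factor; default 0.75.
#' @return Estimated NSP, g/day.
#' @export
nsp_from_aoac <- function(aoac_fibre_g, factor = 0.75) {
  if (any(!is.na(aoac_fibre_g) & aoac_fibre_g < 0)) {
    stop("aoac_fibre_g must be non-negative", call. = FALSE)
  }
  factor * aoac_fibre_g
}

#' Average pedometer step counts over a diary week
#'
#' Arithmetic mean of the non-missing daily counts; a diary with fewer
#' than `min_days` usable days is treated as missing rather than averaged
#' over too thin a base.
#'
#' @param step_counts Numeric vector of (up to 7) daily step counts,
#'   `NA` for unworn days.
#' @param min_days Minimum usable days required; default 4.
#' @return Mean daily steps, or `NA` when below `min_days`.
#' @export
mean_daily_steps <- function(step_counts, min_days = 4) {
  ok <- !is.na(step_counts)
  if (sum(ok) < min_days) return(NA_real_)
  mean(step_counts[ok])
}

#' Convert HbA1c from NGSP percent to IFCC mmol/mol
#'
#' The IFCC/NGSP master-equation linear map,
#' `mmol/mol = 10.93 * % - 23.50`; provided for ingestion of legacy
#' percent-denominated data (the package carries HbA1c in mmol/mol).
#'
#' @param hba1c_pct HbA1c in NGSP percent.
#' @return HbA1c in IFCC mmol/mol.
#' @export
hba1c_pct_to_mmolmol <- function(hba1c_pct) {
  10.93 * hba1c_pct - 23.5
}

#' Derive per-participant analysis variables
#'
#' Turns a raw two-timepoint cohort table into the analysis variables of
#' the chain-graph model: HOMA-IR and HOMA-B at both timepoints, change
#' scores (weight in kg, saturated fat in percentage points of energy,
#' steps in thousands per day) and log-ratio outcomes for HOMA-IR, HOMA-B,
#' glucose and HbA1c. A change score or log ratio is computed only when
#' both timepoints are present (complete-case contract); records missing a
#' required field keep `NA` in the affected columns and the reason is
#' collected in the `exclusions` attribute.
#'
#' Expected columns (suffix `_0` = baseline, `_12` = month 12):
#' `weight_0/weight_12` (kg), `glucose_0/glucose_12` (mmol/L),
#' `insulin_0/insulin_12` (pmol/L), `hba1c_0/hba1c_12` (mmol/mol),
#' `steps_0/steps_12` (mean daily steps), `energy_0/energy_12`,
#' `satfat_g_0/satfat_g_12` (g/day).
#'
#' @param cohort Data frame with an `id` column and the measurement
#'   columns above.
#' @param insulin_conversion,calibration Passed to [homa_indices()].
#' @param energy_unit Passed to [satfat_pct_energy()].
#' @return `cohort` with derived columns appended: `homa_ir_0`,
#'   `homa_ir_12`, `homa_b_0`, `homa_b_12`, `satfat_pct_0`,
#'   `satfat_pct_12`, `d_weight`, `d_satfat_pct`, `d_steps_k`, and
#'   `lr_homa_ir`, `lr_homa_b`, `lr_glucose`, `lr_hba1c`. The
#'   `exclusions` attribute lists ids with missing required fields.
#' @export
derive_changes <- function(cohort, insulin_conversion = 6,
                           calibration = c(ir = 1, b = 1),
                           energy_unit = "kJ") {
  need <- c("id", "weight_0", "weight_12", "glucose_0", "glucose_12",
            "insulin_0", "insulin_12", "hba1c_0", "hba1c_12",
            "steps_0", "steps_12", "energy_0", "energy_12",
            "satfat_g_0", "satfat_g_12")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  h0 <- homa_indices(cohort$glucose_0, cohort$insulin_0,
                     insulin_conversion, calibration)
  h12 <- homa_indices(cohort$glucose_12, cohort$insulin_12,
                      insulin_conversion, calibration)
  cohort$homa_ir_0 <- h0$homa_ir
  cohort$homa_ir_12 <- h12$homa_ir
  cohort$homa_b_0 <- h0$homa_b
  cohort$homa_b_12 <- h12$homa_b
  cohort$satfat_pct_0 <- satfat_pct_energy(cohort$satfat_g_0,
                                           cohort$energy_0,
                                           energy_unit = energy_unit)
  cohort$satfat_pct_12 <- satfat_pct_energy(cohort$satfat_g_12,
                                            cohort$energy_12,
                                            energy_unit = energy_unit)
  both <- function(a, b) ifelse(!is.na(a) & !is.na(b), b - a, NA_real_)
  cohort$d_weight <- both(cohort$weight_0, cohort$weight_12)
  cohort$d_satfat_pct <- both(cohort$satfat_pct_0, cohort$satfat_pct_12)
  cohort$d_steps_k <- both(cohort$steps_0, cohort$steps_12) / 1000
  lr <- function(a, b) ifelse(!is.na(a) & !is.na(b) & a > 0 & b > 0,
                              log(b) - log(a), NA_real_)
  cohort$lr_homa_ir <- lr(cohort$homa_ir_0, cohort$homa_ir_12)
  cohort$lr_homa_b <- lr(cohort$homa_b_0, cohort$homa_b_12)
  cohort$lr_glucose <- lr(cohort$glucose_0, cohort$glucose_12)
  cohort$lr_hba1c <- lr(cohort$hba1c_0, cohort$hba1c_12)
  derived_cols <- c("d_weight", "d_satfat_pct", "d_steps_k",
                    "lr_homa_ir", "lr_homa_b", "lr_glucose", "lr_hba1c")
  incomplete <- cohort$id[rowSums(is.na(cohort[derived_cols])) > 0]
  attr(cohort, "exclusions") <-
    data.frame(id = incomplete,
               reason = "missing timepoint for one or more derived variables",
               stringsAsFactors = FALSE)
  cohort
}
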