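#' Assay design: chip geometry and detector settings
#'
#' Describes the physical layout of a dual-chip kinase activity assay:
#' separate phosphotyrosine (PTK) and serine/threonine (STK) peptide arrays,
#' each read in real time over a fixed number of reaction cycles, with the
#' camera acquiring a ladder of exposures at every cycle. Defaults reproduce
#' the standard configuration: 196 PTK and 144 STK peptide substrates (340
#' total) read over 94 (PTK) and 124 (STK) cycles.
#'
#' @param substrates_per_chip Named integer vector, substrate count per chip
#'   type. Default `c(PTK = 196, STK = 144)`.
#' @param cycles_per_chip Named integer vector, reaction cycles per chip type.
#'   Default `c(PTK = 94, STK = 124)`.
#' @param exposure_times Strictly increasing camera exposure ladder in
#'   milliseconds, length >= 2. Default `c(10, 20, 50, 100, 200)`.
#' @param saturation_level Maximum representable detector intensity in
#'   arbitrary units (AU). Default 65535 (16-bit camera).
#' @param background_level Mean background intensity in AU added to every
#'   spot measurement. Default 150.
#'
#' @return An object of class `assay_design` (a validated list).
#' @examples
#' d <- assay_design()
#' sum(d$substrates_per_chip) # 340
#' @export
assay_design <- function(substrates_per_chip = c(PTK = 196L, STK = 144L),
                         cycles_per_chip = c(PTK = 94L, STK = 124L),
                         exposure_times = c(10, 20, 50, 100, 200),
                         saturation_level = 65535,
                         background_level = 150) {
  chip_types <- names(substrates_per_chip)
  if (is.null(chip_types) || !setequal(chip_types, names(cycles_per_chip))) {
    abort("`substrates_per_chip` and `cycles_per_chip` must share chip-type names.")
  }
  if (any(substrates_per_chip < 1)) abort("Substrate counts must be >= 1.")
  if (any(cycles_per_chip < 2)) abort("Cycle counts must be >= 2.")
  if (length(exposure_times) < 2 || any(diff(exposure_times) <= 0)) {
    abort("`exposure_times` must be strictly increasing with length >= 2.")
  }
  if (!(saturation_level > background_level) || background_level < 0) {
    abort("Require saturation_level > background_level >= 0.")
  }
  structure(
    list(
      chip_types = chip_types,
      substrates_per_chip = substrates_per_chip,
      cycles_per_chip = cycles_per_chip,
      exposure_times = as.numeric(exposure_times),
      saturation_level = saturation_level,
      background_level = background_level
    ),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat("<assay_design>\n")
  cat("  substrates:", paste(names(x$substrates_per_chip), x$substrates_per_chip,
                             sep = "=", collapse = ", "), "\n")
  cat("  cycles:    ", paste(names(x$cycles_per_chip), x$cycles_per_chip,
                             sep = "=", collapse = ", "), "\n")
  cat("  exposures (ms):", paste(x$exposure_times, collapse = ", "), "\n")
  cat("  saturation:", x$saturation_level, " background:", x$background_level, "\n")
  invisible(x)
}

#' Cohort design: patients, tissues, replicates
#'
#' Defines the sample side of a profiling study: a patient cohort with sex
#' labels, paired tumor/adjacent tissue per patient, a technical replicate
#' count, and an optional pooled mode in which equally allocated per-patient
#' lysates are averaged per sex before measurement noise is applied.
#' The default cohort mirrors a 9-patient study (5 male, 4 female) run in
#' technical triplicate.
#'
#' @param patients Data frame with columns `patient_id`, `sex` (`"M"`/`"F"`).
#' @param tissues Character vector of tissue labels. Default
#'   `c("tumor", "adjacent")` (paired design).
#' @param technical_replicates Replicate chips per sample-treatment. Default 3.
#' @param pooled If `TRUE`, per-sex pooled lysates replace individual patients.
#' @return An object of class `cohort_design`.
#' @examples
#' cohort_design() # default 9-patient cohort
#' @export
cohort_design <- function(patients = default_patients(),
                          tissues = c("tumor", "adjacent"),
                          technical_replicates = 3L,
                          pooled = FALSE) {
  patients <- as_tibble(patients)
  stopifnot(all(c("patient_id", "sex") %in% names(patients)))
  if (nrow(patients) < 1) abort("Need >= 1 patient.")
  if (anyDuplicated(patients$patient_id)) abort("Duplicate patient_id.")
  if (!all(patients$sex %in% c("M", "F"))) abort("sex must be 'M' or 'F'.")
  if (technical_replicates < 1) abort("technical_replicates must be >= 1.")
  if (length(tissues) < 1) abort("Need >= 1 tissue.")
  structure(
    list(
      patients = patients,
      tissues = tissues,
      technical_replicates = as.integer(technical_replicates),
      pooled = isTRUE(pooled)
    ),
    class = "cohort_design"
  )
}

#' Default 9-patient cohort (5 male, 4 female)
#'
#' Patient identifiers follow the `HCC-<sex>-<n>` convention.
#' @return A tibble with columns `patient_id`, `sex`.
#' @export
default_patients <- function() {
  tibble(
    patient_id = c(paste0("HCC-M-", 1:5), paste0("HCC-F-", 6:9)),
    sex = c(rep("M", 5), rep("F", 4))
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", nrow(x$patients), "patients (",
      sum(x$patients$sex == "M"), "M /", sum(x$patients$sex == "F"), "F ),",
      x$technical_replicates, "replicates,",
      if (x$pooled) "pooled" else "per-patient", "\n")
  invisible(x)
}

#' Drug panel for on-chip treatment
#'
#' The inhibitor panel added directly to the reagent mix during the array run
#' ("clinical trial on a chip"). Each drug has a nominal target kinase and a
#' final assay concentration; a vehicle entry at concentration 0 is always
#' present. The default panel is the three ABL antagonists at their study
#' concentrations: imatinib 1000 nM, rebastinib 100 nM, olverembatinib 100 nM.
#'
#' @param drugs Data frame with columns `drug_id`, `target_kinase`,
#'   `concentration_nM` (all > 0).
#' @param vehicle_label Label used for the vehicle (DMSO) control. Default
#'   `"vehicle"`.
#' @return An object of class `drug_panel`: a tibble of treatments (vehicle
#'   first, concentration 0) with attributes `vehicle_label`.
#' @examples
#' drug_panel()
#' @export
drug_panel <- function(drugs = default_drugs(), vehicle_label = "vehicle") {
  drugs <- as_tibble(drugs)
  stopifnot(all(c("drug_id", "target_kinase", "concentration_nM") %in% names(drugs)))
  if (any(drugs$concentration_nM <= 0)) abort("Drug concentrations must be > 0.")
  if (anyDuplicated(drugs$drug_id)) abort("Duplicate drug_id.")
  if (vehicle_label %in% drugs$drug_id) abort("vehicle_label collides with a drug_id.")
  out <- bind_rows(
    tibble(drug_id = vehicle_label, target_kinase = NA_character_,
           concentration_nM = 0),
    drugs
  )
  structure(out, class = c("drug_panel", class(out)),
            vehicle_label = vehicle_label)
}

#' Default ABL-inhibitor panel
#' @return A tibble of the three ABL antagonists with assay concentrations.
#' @export
default_drugs <- function() {
  tibble(
    drug_id = c("imatinib", "rebastinib", "olverembatinib"),
    target_kinase = c("ABL1", "ABL1", "ABL1"),
    concentration_nM = c(1000, 100, 100)
  )
}

#' Vehicle label of a drug panel
#' @param panel A `drug_panel`.
#' @return The vehicle treatment label (character scalar).
#' @export
vehicle_label <- function(panel) {
  attr(panel, "vehicle_label") %||% "vehicle"
}
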