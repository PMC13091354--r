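#' Single-site occupancy scaling of kinase activity by an inhibitor
#'
#' Competitive single-site occupancy model: an inhibitor at concentration
#' `concentration` with half-maximal inhibitory concentration `ic50` leaves a
#' fraction `1 / (1 + concentration / ic50)` of the kinase's catalytic
#' activity. At zero dose the activity is unchanged; at `concentration ==
#' ic50` it is exactly halved; the function is monotone non-increasing in
#' concentration.
#'
#' @param activity Kinase activity (AU/ms), > 0. Vectorised.
#' @param concentration Inhibitor concentration in nM, >= 0.
#' @param ic50 IC50 in nM, > 0.
#' @return The scaled activity, same units as `activity`.
#' @examples
#' drug_scaling(10, 50, 50) # 5
#' @export
drug_scaling <- function(activity, concentration, ic50) {
  if (any(ic50 <= 0)) abort("`ic50` must be > 0.")
  if (any(concentration < 0)) abort("`concentration` must be >= 0.")
  if (any(activity <= 0)) abort("`activity` must be > 0.")
  activity / (1 + concentration / ic50)
}

# Occupancy fraction retained for each (kinase, drug); 1 when no interaction.
.occupancy_table <- function(truth, panel) {
  panel |>
    as_tibble() |>
    select("drug_id", "concentration_nM") |>
    inner_join(truth$drug_ic50, by = "drug_id", relationship = "many-to-many") |>
    mutate(occupancy = 1 / (1 + .data$concentration_nM / .data$ic50_nM)) |>
    select("kinase_id", "drug_id", "occupancy")
}

# Noiseless per-spot velocity V for every substrate x unit x treatment.
# units: tibble(patient_id, sex, tissue). Non-responder overrides invert the
# occupancy effect (factor 2 - f) for the listed (patient, drug, kinase).
.velocity_table <- function(map, truth, panel, units) {
  base <- select(truth$baseline_activity, "kinase_id", "baseline")
  missing_k <- setdiff(map$edges$kinase_id, base$kinase_id)
  if (length(missing_k) > 0) {
    abort(paste0("Ground truth lacks baseline activity for kinase: ", missing_k[1]))
  }
  missing_s <- setdiff(map$substrates$substrate_id, truth$kinetic_rate$substrate_id)
  if (length(missing_s) > 0) {
    abort(paste0("Ground truth lacks kinetic rate for substrate: ", missing_s[1]))
  }
  occ <- .occupancy_table(truth, panel)
  treatments <- select(as_tibble(panel), "drug_id")

  contrib <- map$edges |>
    left_join(base, by = "kinase_id") |>
    expand_grid(distinct(units, .data$patient_id, .data$sex, .data$tissue)) |>
    left_join(truth$condition_multipliers,
              by = c("kinase_id", "tissue", "sex")) |>
    mutate(multiplier = dplyr::coalesce(.data$multiplier, 1)) |>
    expand_grid(treatments) |>
    left_join(occ, by = c("kinase_id", "drug_id")) |>
    mutate(occupancy = dplyr::coalesce(.data$occupancy, 1))

  if (nrow(truth$non_responders) > 0) {
    contrib <- contrib |>
      left_join(mutate(truth$non_responders, .invert = TRUE),
                by = c("patient_id", "drug_id", "kinase_id")) |>
      mutate(occupancy = ifelse(dplyr::coalesce(.data$.invert, FALSE),
                                2 - .data$occupancy, .data$occupancy)) |>
      select(-".invert")
  }

  contrib |>
    group_by(.data$substrate_id, .data$patient_id, .data$sex, .data$tissue,
             treatment = .data$drug_id) |>
    summarise(velocity = sum(.data$weight * .data$baseline *
                               .data$multiplier * .data$occupancy),
              .groups = "drop")
}

# Resolve measurement units: individual patients, or per-sex pools whose
# velocities are the equal-allocation mean of the sex's patients.
.cohort_units <- function(cohort) {
  tibble(patient_id = cohort$patients$patient_id,
         sex = cohort$patients$sex) |>
    expand_grid(tissue = cohort$tissues)
}

#' Simulate a raw multi-cycle, multi-exposure signal table
#'
#' Emulates the real-time acquisition of a PamChip-style run. For each
#' substrate, sample and treatment the effective phosphorylation velocity is
#' the weighted sum over annotated kinases of baseline activity times the
#' tissue/sex condition multiplier times the drug occupancy factor
#' ([drug_scaling()]). The kinetic signal at reaction cycle `c` follows a
#' saturating exponential `A(c) = V * (1 - exp(-r_s * c))`, and the recorded
#' spot intensity at camera exposure `e` is
#' `clip(background + e * A(c) * spot_noise * replicate_noise + eps, 0,
#' saturation)` with multiplicative lognormal spot and replicate-chip effects
#' (unit mean) and additive Gaussian background noise. Pooled cohorts average
#' the per-patient noiseless velocities per sex (equal allocation) before
#' noise. Deterministic given `seed`.
#'
#' @param design An [assay_design()].
#' @param map A [kinase_substrate_map()].
#' @param truth A [ground_truth()].
#' @param cohort A [cohort_design()].
#' @param panel A [drug_panel()].
#' @param seed Non-negative integer seed.
#' @return A tibble of class `raw_signals` with columns `substrate_id`,
#'   `chip_type`, `patient_id`, `sex`, `tissue`, `treatment`, `replicate`,
#'   `cycle`, `exposure_ms`, `intensity`, carrying the design as an
#'   attribute. The grid is complete: one row per substrate x sample x
#'   treatment x replicate x cycle x exposure.
#' @export
simulate_signals <- function(design, map, truth, cohort, panel, seed = 0) {
  stopifnot(inherits(design, "assay_design"), inherits(map, "kinase_substrate_map"),
            inherits(truth, "ground_truth"), inherits(cohort, "cohort_design"),
            inherits(panel, "drug_panel"))
  targets <- setdiff(unique(as_tibble(panel)$target_kinase), NA)
  missing_t <- setdiff(targets, map$kinases$kinase_id)
  if (length(missing_t) > 0) {
    abort(paste0("Drug panel targets kinase absent from annotation: ", missing_t[1]))
  }
  bad_ic50 <- setdiff(truth$drug_ic50$drug_id, as_tibble(panel)$drug_id)
  if (length(bad_ic50) > 0) {
    abort(paste0("IC50 table references drug absent from panel: ", bad_ic50[1]))
  }

  units <- .cohort_units(cohort)
  vel <- .velocity_table(map, truth, panel, units)
  if (cohort$pooled) {
    vel <- vel |>
      group_by(.data$substrate_id, .data$sex, .data$tissue, .data$treatment) |>
      summarise(velocity = mean(.data$velocity), .groups = "drop") |>
      mutate(patient_id = paste0("POOL_", .data$sex))
  }

  vel <- vel |>
    left_join(map$substrates, by = "substrate_id") |>
    left_join(truth$kinetic_rate, by = "substrate_id") |>
    arrange(.data$chip_type, .data$substrate_id, .data$patient_id,
            .data$tissue, .data$treatment)

  spots <- expand_grid(vel, replicate = seq_len(cohort$technical_replicates))
  noise <- truth$noise
  lnorm_mult <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  out <- withr::with_seed(as.integer(seed), {
    rep_units <- spots |>
      distinct(.data$patient_id, .data$tissue, .data$treatment, .data$replicate) |>
      arrange(.data$patient_id, .data$tissue, .data$treatment, .data$replicate)
    rep_units$rep_effect <- lnorm_mult(nrow(rep_units), noise$replicate_cv)
    spots <- left_join(spots, rep_units,
                       by = c("patient_id", "tissue", "treatment", "replicate"))
    spots$spot_effect <- lnorm_mult(nrow(spots), noise$spot_cv)

    long <- spots |>
      mutate(.n_cycles = design$cycles_per_chip[.data$chip_type]) |>
      mutate(cycle = purrr::map(.data$.n_cycles, seq_len)) |>
      select(-".n_cycles") |>
      unnest("cycle") |>
      mutate(kinetic = .data$velocity * (1 - exp(-.data$rate * .data$cycle))) |>
      expand_grid(exposure_ms = design$exposure_times)

    eps <- if (noise$background_sd > 0) {
      stats::rnorm(nrow(long), 0, noise$background_sd)
    } else 0
    long$intensity <- pmin(pmax(design$background_level +
                                  long$exposure_ms * long$kinetic *
                                  long$spot_effect * long$rep_effect + eps,
                                0), design$saturation_level)
    long
  })

  out <- out |>
    select("substrate_id", "chip_type", "patient_id", "sex", "tissue",
           "treatment", "replicate", "cycle", "exposure_ms", "intensity")
  attr(out, "design") <- design
  class(out) <- c("raw_signals", class(out))
  out
}

#' Analytic PerMed score from ground truth (noiseless oracle)
#'
#' Computes the PerMed score a noiseless run would yield, directly from the
#' generative model: for each substrate mapped to `kinase`, the percent
#' change of its noiseless end-level signal under the drug versus vehicle.
#' Because the kinetic factor is treatment-independent it cancels, leaving
#' the percent change of effective velocities. Used as the recovery target
#' for [permed_score()].
#'
#' @param map A [kinase_substrate_map()].
#' @param truth A [ground_truth()].
#' @param panel A [drug_panel()].
#' @param kinase Kinase whose substrates are scored.
#' @param drug Drug in the panel.
#' @param tissue,sex Optional condition context for the multipliers; default
#'   none (multipliers 1).
#' @param patient_id Optional patient context so non-responder overrides
#'   apply.
#' @return The analytic PerMed score in percent (mean over mapped substrates
#'   of `100 * (treated - vehicle) / vehicle`).
#' @export
truth_permed <- function(map, truth, panel, kinase, drug,
                         tissue = NA_character_, sex = NA_character_,
                         patient_id = "ref") {
  panel_tbl <- as_tibble(panel)
  if (!drug %in% panel_tbl$drug_id) abort(paste0("Unknown drug: ", drug))
  subs <- map$edges$substrate_id[map$edges$kinase_id == kinase]
  if (length(subs) == 0) {
    abort(paste0("Kinase has no mapped substrates: ", kinase))
  }
  units <- tibble(patient_id = patient_id, sex = sex, tissue = tissue)
  vel <- .velocity_table(map, truth, panel, units) |>
    filter(.data$substrate_id %in% subs,
           .data$treatment %in% c(drug, vehicle_label(panel)))
  wide <- pivot_wider(vel, id_cols = "substrate_id",
                      names_from = "treatment", values_from = "velocity")
  mean(100 * (wide[[drug]] - wide[[vehicle_label(panel)]]) /
         wide[[vehicle_label(panel)]])
}

#' Write / read a raw signal table as TSV
#'
#' Long-format interchange for [simulate_signals()] output; `read_signals()`
#' is gzip-transparent via readr.
#'
#' @param raw A `raw_signals` tibble.
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_signals <- function(raw, path) {
  readr::write_tsv(raw, path)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    substrate_id = readr::col_character(),
    chip_type = readr::col_character(),
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    tissue = readr::col_character(),
    treatment = readr::col_character(),
    replicate = readr::col_integer(),
    cycle = readr::col_integer(),
    exposure_ms = readr::col_double(),
    intensity = readr::col_double()
  ), comment = "#")
}
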