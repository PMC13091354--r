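#' Ground-truth kinase activities for simulation
#'
#' The mechanistic parameters behind a simulated profiling run: per-kinase
#' baseline catalytic activity, multiplicative tissue/sex condition effects,
#' drug-kinase IC50s for the occupancy model, per-substrate first-order
#' phosphorylation rate constants, and noise magnitudes. An optional
#' non-responder table inverts a drug's effect on its target kinase for the
#' listed patients, emulating patients whose target activity rises under an
#' inhibitor.
#'
#' @param baseline_activity Tibble `kinase_id`, `baseline` (AU/ms per cycle
#'   unit, > 0).
#' @param condition_multipliers Tibble `kinase_id`, `tissue`, `sex`,
#'   `multiplier` (> 0). Absent combinations default to 1.
#' @param drug_ic50 Tibble `kinase_id`, `drug_id`, `ic50_nM` (> 0). Absent
#'   pairs mean no interaction.
#' @param kinetic_rate Tibble `substrate_id`, `rate` (per-cycle first-order
#'   rate constant, > 0).
#' @param noise List with `spot_cv`, `replicate_cv` (coefficients of
#'   variation in `[0, 1)`) and `background_sd` (AU, >= 0).
#' @param non_responders Tibble `patient_id`, `drug_id`, `kinase_id` (may be
#'   empty).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(baseline_activity,
                         condition_multipliers = NULL,
                         drug_ic50 = NULL,
                         kinetic_rate,
                         noise = list(spot_cv = 0.10, replicate_cv = 0.05,
                                      background_sd = 5),
                         non_responders = NULL) {
  baseline_activity <- as_tibble(baseline_activity)
  kinetic_rate <- as_tibble(kinetic_rate)
  empty_mult <- tibble(kinase_id = character(), tissue = character(),
                       sex = character(), multiplier = numeric())
  empty_ic50 <- tibble(kinase_id = character(), drug_id = character(),
                       ic50_nM = numeric())
  empty_nr <- tibble(patient_id = character(), drug_id = character(),
                     kinase_id = character())
  condition_multipliers <- as_tibble(condition_multipliers %||% empty_mult)
  drug_ic50 <- as_tibble(drug_ic50 %||% empty_ic50)
  non_responders <- as_tibble(non_responders %||% empty_nr)

  if (any(baseline_activity$baseline <= 0)) abort("Baseline activities must be > 0.")
  if (any(kinetic_rate$rate <= 0)) abort("Kinetic rates must be > 0.")
  if (nrow(drug_ic50) > 0 && any(drug_ic50$ic50_nM <= 0)) abort("IC50s must be > 0.")
  if (nrow(condition_multipliers) > 0 && any(condition_multipliers$multiplier <= 0)) {
    abort("Condition multipliers must be > 0.")
  }
  cvs <- c(noise$spot_cv, noise$replicate_cv)
  if (any(cvs < 0 | cvs >= 1) || noise$background_sd < 0) {
    abort("Noise CVs must lie in [0, 1) and background_sd >= 0.")
  }
  structure(
    list(baseline_activity = baseline_activity,
         condition_multipliers = condition_multipliers,
         drug_ic50 = drug_ic50,
         kinetic_rate = kinetic_rate,
         noise = noise,
         non_responders = non_responders),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$baseline_activity), "kinases,",
      nrow(x$kinetic_rate), "substrates,",
      nrow(x$drug_ic50), "drug-kinase interactions\n")
  cat("  noise: spot_cv=", x$noise$spot_cv, " replicate_cv=", x$noise$replicate_cv,
      " background_sd=", x$noise$background_sd, "\n", sep = "")
  invisible(x)
}

#' Default ground truth for the standard HCC-style cohort simulation
#'
#' Baseline kinase activities are lognormal (median 1.2 AU/ms, sdlog 0.5);
#' substrate rate constants are Uniform(0.02, 0.10) per cycle. Condition
#' effects script the study's biology: ABL1/ABL2 up in tumor in both sexes,
#' AKT1/AKT2 up in male tumors but down in female tumors, INSR strongly up in
#' female tumors, SYK moderately up in both. The drug-IC50 table gives the
#' three ABL antagonists their target affinities plus plausible off-target
#' interactions (imatinib also inhibits DDR1; rebastinib DDR1 and FRK;
#' olverembatinib SRC and FRK). Noise defaults: 10% spot CV, 5% replicate CV,
#' background SD 5 AU.
#'
#' @param map A [kinase_substrate_map()] supplying the kinase and substrate
#'   universe.
#' @param seed Non-negative integer seed.
#' @param noise Noise list as in [ground_truth()].
#' @param non_responders Optional non-responder override table.
#' @return A [ground_truth()].
#' @export
build_default_truth <- function(map, seed = 0,
                                noise = list(spot_cv = 0.10, replicate_cv = 0.05,
                                             background_sd = 5),
                                non_responders = NULL) {
  stopifnot(inherits(map, "kinase_substrate_map"))
  withr::with_seed(as.integer(seed), {
    baseline <- tibble(
      kinase_id = map$kinases$kinase_id,
      baseline = stats::rlnorm(nrow(map$kinases), meanlog = log(1.2), sdlog = 0.5)
    )
    rates <- tibble(
      substrate_id = map$substrates$substrate_id,
      rate = stats::runif(nrow(map$substrates), 0.02, 0.10)
    )
  })
  mult <- bind_rows(
    expand_grid(kinase_id = c("ABL1", "ABL2"), tissue = "tumor",
                sex = c("M", "F"), multiplier = 2.5),
    expand_grid(kinase_id = c("AKT1", "AKT2"), tissue = "tumor") |>
      mutate(sex = list(c("M", "F"))) |> unnest("sex") |>
      mutate(multiplier = ifelse(.data$sex == "M", 1.8, 0.6)),
    tibble(kinase_id = "INSR", tissue = "tumor", sex = "F", multiplier = 2.8),
    expand_grid(kinase_id = "SYK", tissue = "tumor", sex = c("M", "F"),
                multiplier = 1.6)
  )
  mult <- semi_join(mult, map$kinases, by = "kinase_id")
  ic50 <- tibble(
    kinase_id = c("ABL1", "ABL2", "DDR1",
                  "ABL1", "ABL2", "DDR1", "FRK",
                  "ABL1", "ABL2", "SRC", "FRK"),
    drug_id = c(rep("imatinib", 3), rep("rebastinib", 4), rep("olverembatinib", 4)),
    ic50_nM = c(250, 300, 120,
                30, 40, 60, 500,
                10, 15, 25, 60)
  )
  ic50 <- semi_join(ic50, map$kinases, by = "kinase_id")
  ground_truth(baseline, mult, ic50, rates, noise, non_responders)
}
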