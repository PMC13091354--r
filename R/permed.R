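#' PerMed score: per-kinase mean percent change versus control
#'
#' The PerMed score of a kinase under a treatment contrast is the mean, over
#' its mapped and measured substrates, of the percent change of the
#' background-subtracted linear signal relative to the control:
#' `pct_s = 100 * (treat_s - ctrl_s) / ctrl_s`. Substrates whose control
#' signal has magnitude below `epsilon` (an unstable denominator) or whose
#' value is masked are excluded and listed with a reason. Because the signal
#' is background-subtracted, treated signals may be negative and scores below
#' -100% are legal. When several samples are present, treated and control
#' signals are averaged per substrate across samples first.
#'
#' @param matrix A *linear-scale* `quantified_signals` tibble containing both
#'   contrast labels.
#' @param map A [kinase_substrate_map()].
#' @param kinase Kinase id (must have at least one usable substrate).
#' @param treat_label,ctrl_label Treatment labels contrasted.
#' @param epsilon Denominator guard in AU/ms (default 1e-3).
#' @return A tibble of class `permed_report`, one row per scored substrate
#'   (`substrate_id`, `ctrl`, `treat`, `pct`); attributes `kinase`, `score`
#'   (the PerMed score in percent), `n_substrates`, `contrast`, `excluded`
#'   (tibble of excluded substrates with reasons), `signal_scale`.
#'   [glance()] returns the one-row summary.
#' @examples
#' # ctrl = (10, 20, 40), treat = (5, 10, 60) -> pcts (-50, -50, +50),
#' # score -16.67%
#' @export
permed_score <- function(matrix, map, kinase, treat_label, ctrl_label,
                         epsilon = 1e-3) {
  if (signal_scale(matrix) != "linear") {
    abort("PerMed is computed on the linear background-subtracted scale.")
  }
  m <- as_tibble(matrix)
  for (lab in c(treat_label, ctrl_label)) {
    if (!lab %in% m$treatment) abort(paste0("Treatment label absent: ", lab))
  }
  mapped <- map$edges$substrate_id[map$edges$kinase_id == kinase]
  if (length(mapped) == 0) {
    abort(paste0("Kinase has no mapped substrates: ", kinase),
          class = "kinomechip_unscorable")
  }
  wide <- m |>
    filter(.data$substrate_id %in% mapped,
           .data$treatment %in% c(treat_label, ctrl_label)) |>
    group_by(.data$substrate_id, .data$treatment) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    pivot_wider(names_from = "treatment", values_from = "value") |>
    rename(ctrl = all_of(ctrl_label), treat = all_of(treat_label))
  if (nrow(wide) == 0) {
    abort(paste0("No measured substrates for kinase: ", kinase),
          class = "kinomechip_unscorable")
  }
  wide <- mutate(wide, reason = dplyr::case_when(
    is.na(.data$ctrl) | is.na(.data$treat) ~ "masked",
    abs(.data$ctrl) < epsilon ~ "control_below_epsilon",
    TRUE ~ NA_character_
  ))
  excluded <- wide |> filter(!is.na(.data$reason)) |>
    select("substrate_id", "reason")
  used <- wide |> filter(is.na(.data$reason)) |> select(-"reason") |>
    mutate(pct = 100 * (.data$treat - .data$ctrl) / .data$ctrl) |>
    arrange(.data$substrate_id)
  if (nrow(used) == 0) {
    abort(paste0("All substrates excluded for kinase ", kinase,
                 "; PerMed undefined."),
          class = "kinomechip_unscorable")
  }
  attr(used, "kinase") <- kinase
  attr(used, "score") <- mean(used$pct)
  attr(used, "n_substrates") <- nrow(used)
  attr(used, "contrast") <- paste0(treat_label, "-vs-", ctrl_label)
  attr(used, "excluded") <- excluded
  attr(used, "signal_scale") <- "linear_background_subtracted"
  attr(used, "epsilon") <- epsilon
  class(used) <- unique(c("permed_report", class(used)))
  used
}

#' PerMed score value of a report
#' @param report A `permed_report`.
#' @return The score in percent.
#' @export
permed_value <- function(report) attr(report, "score")

#' @export
print.permed_report <- function(x, ...) {
  cat("<permed_report> ", attr(x, "kinase"), " ", attr(x, "contrast"),
      ": score = ", sprintf("%.2f%%", attr(x, "score")),
      " over ", attr(x, "n_substrates"), " substrates",
      if (nrow(attr(x, "excluded")) > 0) {
        paste0(" (", nrow(attr(x, "excluded")), " excluded)")
      }, "\n", sep = "")
  NextMethod()
}

#' Off-target calls from a kinase score table
#'
#' Kinases other than the drug's nominal target whose PerMed magnitude meets
#' the threshold, sorted by `|score|` descending. Direction is retained, so
#' compensatory *increases* in other pathways are reported as positive
#' scores.
#'
#' @param scores Tibble with columns `kinase_id`, `score` sharing one
#'   contrast.
#' @param target_kinase The nominal target to exclude.
#' @param threshold Magnitude threshold in percent (default 20).
#' @return The filtered, sorted tibble.
#' @export
detect_off_target <- function(scores, target_kinase, threshold = 20) {
  scores |>
    filter(.data$kinase_id != target_kinase,
           abs(.data$score) >= threshold) |>
    arrange(desc(abs(.data$score)))
}

#' Run the clinical-trial-on-a-chip comparison
#'
#' For every analysis unit (patient x tissue, or pooled group) and every drug
#' in the panel, computes PerMed scores versus vehicle for all scorable
#' kinases, extracts the nominal target's score, calls off-targets
#' (`|score| >= off_target_threshold`, excluding the target) and
#' non-responders (strictly positive target PerMed under an inhibitor), and
#' ranks the drugs per unit ([rank_drugs()]).
#'
#' @param matrix A linear-scale `quantified_signals` tibble containing
#'   vehicle and the panel drugs.
#' @param map A [kinase_substrate_map()].
#' @param panel A [drug_panel()].
#' @param off_target_threshold Percent threshold for off-target calls
#'   (default 20).
#' @param epsilon PerMed denominator guard (default 1e-3 AU/ms).
#' @param min_substrates Minimum usable substrates for a kinase to be scored
#'   (default 3).
#' @return An object of class `trial_report`: a list with `scores` (long
#'   tibble: unit, drug, kinase, score, n_substrates), `summary` (per unit x
#'   drug: target kinase/score, off-target count, non-responder flag),
#'   `off_targets` (long tibble of calls) and `ranking` (per unit,
#'   [rank_drugs()] order). [tidy()] returns `scores`; [glance()] returns
#'   `summary`.
#' @export
run_trial <- function(matrix, map, panel, off_target_threshold = 20,
                      epsilon = 1e-3, min_substrates = 3) {
  veh <- vehicle_label(panel)
  m <- as_tibble(matrix)
  if (!veh %in% m$treatment) {
    abort(paste0("Vehicle treatment absent from matrix: ", veh))
  }
  panel_tbl <- filter(as_tibble(panel), .data$drug_id != veh)
  drugs_present <- intersect(panel_tbl$drug_id, unique(m$treatment))
  not_assayed <- setdiff(panel_tbl$drug_id, drugs_present)

  units <- m |> distinct(.data$patient_id, .data$tissue) |>
    mutate(unit = paste(.data$patient_id, .data$tissue, sep = "|"))
  measured <- unique(m$substrate_id)
  mapped_sets <- split(map$edges$substrate_id, map$edges$kinase_id)
  n_usable <- vapply(mapped_sets, function(s) length(intersect(s, measured)),
                     integer(1))
  kinases <- sort(names(mapped_sets)[n_usable >= min_substrates])

  scores <- purrr::pmap(units, function(patient_id, tissue, unit) {
    sub <- filter(m, .data$patient_id == .env$patient_id,
                  .data$tissue == .env$tissue)
    sub <- new_quantified(sub, "linear", attr(matrix, "params"),
                          attr(matrix, "design"))
    purrr::map(drugs_present, function(d) {
      rows <- purrr::map(kinases, function(k) {
        rep <- tryCatch(
          permed_score(sub, map, k, treat_label = d, ctrl_label = veh,
                       epsilon = epsilon),
          kinomechip_unscorable = function(e) NULL
        )
        if (is.null(rep) || attr(rep, "n_substrates") < min_substrates) {
          return(NULL)
        }
        tibble(unit = unit, drug_id = d, kinase_id = k,
               score = permed_value(rep),
               n_substrates = attr(rep, "n_substrates"))
      })
      bind_rows(rows)
    }) |> bind_rows()
  }) |> bind_rows()

  if (nrow(scores) == 0) abort("No scorable (unit, drug, kinase) triples.")

  targets <- select(panel_tbl, "drug_id", "target_kinase")
  summary <- scores |>
    inner_join(targets, by = "drug_id") |>
    group_by(.data$unit, .data$drug_id, .data$target_kinase) |>
    summarise(
      target_permed = {
        hit <- .data$score[.data$kinase_id == .data$target_kinase[1]]
        if (length(hit) == 0) NA_real_ else hit[1]
      },
      .groups = "drop"
    )

  off <- scores |>
    inner_join(targets, by = "drug_id") |>
    group_by(.data$unit, .data$drug_id) |>
    dplyr::group_modify(function(d, key) {
      detect_off_target(d, d$target_kinase[1], off_target_threshold)
    }) |>
    ungroup() |>
    select("unit", "drug_id", "kinase_id", "score")

  summary <- summary |>
    left_join(count(off, .data$unit, .data$drug_id, name = "n_off_targets"),
              by = c("unit", "drug_id")) |>
    left_join(off |> group_by(.data$unit, .data$drug_id) |>
                summarise(off_target_abs_sum = sum(abs(.data$score)),
                          .groups = "drop"),
              by = c("unit", "drug_id")) |>
    mutate(n_off_targets = dplyr::coalesce(.data$n_off_targets, 0L),
           off_target_abs_sum = dplyr::coalesce(.data$off_target_abs_sum, 0),
           non_responder = !is.na(.data$target_permed) & .data$target_permed > 0)

  out <- structure(
    list(scores = scores, summary = summary, off_targets = off,
         ranking = NULL, not_assayed = not_assayed,
         params = list(off_target_threshold = off_target_threshold,
                       epsilon = epsilon, min_substrates = min_substrates,
                       vehicle = veh)),
    class = "trial_report"
  )
  out$ranking <- rank_drugs(out)
  out
}

#' Rank the drugs of a trial report per analysis unit
#'
#' Ordering rules, per unit: non-responder drugs last regardless; otherwise
#' most negative target PerMed first; ties by fewer off-target calls, then by
#' smaller summed off-target magnitude, then drug id.
#'
#' @param trial A `trial_report` (or its `summary` tibble).
#' @return A tibble `unit`, `drug_id`, `drug_rank` (1 = preferred).
#' @export
rank_drugs <- function(trial) {
  s <- if (inherits(trial, "trial_report")) trial$summary else as_tibble(trial)
  if (nrow(s) == 0) abort("No scored drugs to rank.")
  s |>
    group_by(.data$unit) |>
    arrange(.data$non_responder, .data$target_permed, .data$n_off_targets,
            .data$off_target_abs_sum, .data$drug_id, .by_group = TRUE) |>
    mutate(drug_rank = dplyr::row_number()) |>
    ungroup() |>
    select("unit", "drug_id", "drug_rank")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report> off-target threshold ", x$params$off_target_threshold,
      "%, epsilon ", x$params$epsilon, " AU/ms\n", sep = "")
  print(x$summary)
  if (length(x$not_assayed) > 0) {
    cat("not assayed:", paste(x$not_assayed, collapse = ", "), "\n")
  }
  invisible(x)
}
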