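#' Exposure-slope quantification of one spot at one cycle
#'
#' Multi-exposure quantification: a spot imaged at several camera exposures
#' yields intensities proportional to exposure time until the detector
#' saturates. The spot signal is the background-corrected least-squares slope
#' through the origin of intensity versus exposure, computed after discarding
#' saturated points (`intensity >= saturation`). At least two unsaturated
#' points must survive.
#'
#' @param intensities Numeric vector of spot intensities (AU).
#' @param exposures Strictly increasing exposure times (ms), same length.
#' @param saturation Detector saturation level (AU).
#' @param background Background intensity subtracted before the fit (AU).
#' @return Slope in AU/ms.
#' @examples
#' fit_exposure_slope(c(100, 200, 500, 1000, 2000), c(10, 20, 50, 100, 200),
#'                    saturation = 65535) # 10
#' @export
fit_exposure_slope <- function(intensities, exposures, saturation,
                               background = 0) {
  if (length(intensities) != length(exposures) || length(exposures) < 2) {
    abort("Need intensity/exposure vectors of equal length >= 2.")
  }
  if (any(diff(exposures) <= 0)) abort("`exposures` must be strictly increasing.")
  keep <- intensities < saturation
  if (sum(keep) < 2) {
    abort("All (or all but one) points saturated; slope undefined.",
          class = "kinomechip_saturated")
  }
  e <- exposures[keep]
  y <- intensities[keep] - background
  sum(e * y) / sum(e * e)
}

#' End-level statistic of a kinetic series
#'
#' The quantified activity of a spot is taken at the end of the real-time
#' read: the mean of the last `window` per-cycle slopes. Missing values
#' (saturated cycles) are dropped; if the whole window is missing the result
#' is `NA`.
#'
#' @param series Numeric vector of per-cycle signals (AU/ms), cycle order.
#' @param window Number of trailing cycles to average, `1 <= window <=
#'   length(series)`. Default 10.
#' @return Mean of the last `window` values (AU/ms).
#' @examples
#' kinetic_endlevel(1:94, window = 1) # 94
#' @export
kinetic_endlevel <- function(series, window = 10) {
  n <- length(series)
  if (n == 0) abort("Empty kinetic series.")
  if (window < 1 || window > n) abort("`window` must lie in [1, length(series)].")
  tail_vals <- series[(n - window + 1):n]
  if (all(is.na(tail_vals))) return(NA_real_)
  mean(tail_vals, na.rm = TRUE)
}

#' Quantify a raw signal table into a substrate-by-sample activity matrix
#'
#' Per (substrate, sample, treatment, replicate): an exposure slope is fitted
#' at every cycle ([fit_exposure_slope()]; cycles with fewer than two
#' unsaturated points yield `NA`), the end-level over the trailing `window`
#' cycles is taken ([kinetic_endlevel()]), and replicates are collapsed by
#' arithmetic mean. Each cell receives exactly one QC flag:
#' `saturated` (any replicate's end-level undefined), `high_cv` (replicate
#' CV above `cv_threshold`), `low_signal` (mean end-level below
#' `low_signal_floor`), else `ok`. With `transform = "log2"` values are
#' floored at `log2_floor` before the log so fold changes stay finite.
#'
#' @param raw A `raw_signals` tibble (from [simulate_signals()] or
#'   [read_signals()]).
#' @param design The [assay_design()] used (defaults to the attribute carried
#'   by `raw`); supplies background, saturation and expected grid.
#' @param window End-level window in cycles (default 10).
#' @param transform `"linear"` (default) or `"log2"`.
#' @param low_signal_floor AU/ms floor under which a cell is flagged
#'   `low_signal` (default 0.01).
#' @param cv_threshold Replicate CV above which a cell is flagged `high_cv`
#'   (default 0.5).
#' @param log2_floor Linear floor applied before log2 (default 1e-3 AU/ms).
#' @return A tibble of class `quantified_signals` with one row per cell:
#'   `substrate_id`, `chip_type`, `patient_id`, `sex`, `tissue`, `treatment`,
#'   `value`, `qc_flag`, `n_replicates`, `replicate_cv`; attributes
#'   `transform`, `params`, `design`.
#' @export
quantify <- function(raw, design = attr(raw, "design"), window = 10,
                     transform = c("linear", "log2"),
                     low_signal_floor = 0.01, cv_threshold = 0.5,
                     log2_floor = 1e-3) {
  transform <- match.arg(transform)
  if (is.null(design)) abort("`design` required (raw table carries none).")
  .check_grid(raw, design)

  n_exp <- length(design$exposure_times)
  sat <- design$saturation_level
  bg <- design$background_level

  # vectorised through-origin slope per (spot, cycle), saturated points dropped
  slopes <- raw |>
    mutate(.unsat = .data$intensity < sat,
           .ey = ifelse(.data$.unsat, .data$exposure_ms * (.data$intensity - bg), 0),
           .e2 = ifelse(.data$.unsat, .data$exposure_ms^2, 0)) |>
    group_by(.data$substrate_id, .data$chip_type, .data$patient_id, .data$sex,
             .data$tissue, .data$treatment, .data$replicate, .data$cycle) |>
    summarise(.n_unsat = sum(.data$.unsat), .sey = sum(.data$.ey),
              .se2 = sum(.data$.e2), .groups = "drop") |>
    mutate(slope = ifelse(.data$.n_unsat >= 2, .data$.sey / .data$.se2, NA_real_))

  # end-level: mean slope over the trailing `window` cycles of each spot
  endlevels <- slopes |>
    mutate(.n_cycles = unname(design$cycles_per_chip[.data$chip_type])) |>
    filter(.data$cycle > .data$.n_cycles - pmin(window, .data$.n_cycles)) |>
    group_by(.data$substrate_id, .data$chip_type, .data$patient_id, .data$sex,
             .data$tissue, .data$treatment, .data$replicate) |>
    summarise(endlevel = mean(.data$slope, na.rm = TRUE),
              any_sat = anyNA(.data$slope), .groups = "drop") |>
    mutate(endlevel = ifelse(is.nan(.data$endlevel), NA_real_, .data$endlevel))

  cells <- endlevels |>
    group_by(.data$substrate_id, .data$chip_type, .data$patient_id, .data$sex,
             .data$tissue, .data$treatment) |>
    summarise(
      value = mean(.data$endlevel),
      replicate_cv = {
        m <- mean(.data$endlevel)
        s <- sd(.data$endlevel)
        if (is.na(m) || is.na(s) || s == 0) 0 else s / abs(m)
      },
      n_replicates = n(),
      any_sat = any(.data$any_sat),
      .groups = "drop"
    ) |>
    mutate(qc_flag = dplyr::case_when(
      .data$any_sat | is.na(.data$value) ~ "saturated",
      .data$replicate_cv > cv_threshold ~ "high_cv",
      .data$value < low_signal_floor ~ "low_signal",
      TRUE ~ "ok"
    )) |>
    select(-"any_sat")

  if (transform == "log2") {
    cells <- mutate(cells, value = log2(pmax(.data$value, log2_floor)))
  }
  params <- list(window = window, low_signal_floor = low_signal_floor,
                 cv_threshold = cv_threshold, log2_floor = log2_floor,
                 n_exposures = n_exp)
  new_quantified(cells, transform, params, design)
}

new_quantified <- function(cells, transform, params, design) {
  attr(cells, "transform") <- transform
  attr(cells, "params") <- params
  attr(cells, "design") <- design
  class(cells) <- unique(c("quantified_signals", class(cells)))
  cells
}

#' Construct a quantified matrix from a plain table
#'
#' Wraps an existing table of quantified signals (e.g. imported from another
#' quantification tool) as a `quantified_signals` object so the downstream
#' statistics apply. Requires columns `substrate_id`, `chip_type`,
#' `patient_id`, `tissue`, `treatment`, `value`; `sex`, `qc_flag`,
#' `n_replicates`, `replicate_cv` are filled with defaults when absent.
#'
#' @param df A data frame of quantified signals.
#' @param transform `"linear"` or `"log2"` — the scale `value` is on.
#' @param design Optional [assay_design()] attached as metadata.
#' @return A `quantified_signals` tibble.
#' @export
as_quantified <- function(df, transform = c("linear", "log2"), design = NULL) {
  transform <- match.arg(transform)
  df <- as_tibble(df)
  need <- c("substrate_id", "chip_type", "patient_id", "tissue", "treatment",
            "value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  if (!"qc_flag" %in% names(df)) df$qc_flag <- "ok"
  if (!"n_replicates" %in% names(df)) df$n_replicates <- 1L
  if (!"replicate_cv" %in% names(df)) df$replicate_cv <- 0
  new_quantified(df, transform, list(), design)
}

#' Signal scale of a quantified matrix
#' @param x A `quantified_signals` tibble.
#' @return `"linear"` or `"log2"`.
#' @export
signal_scale <- function(x) attr(x, "transform") %||% "linear"

#' Convert a linear quantified matrix to log2
#'
#' Applies `log2(pmax(value, floor))`; the floor keeps fold changes finite.
#' @param x A linear-scale `quantified_signals` tibble.
#' @param floor Linear floor before the log (default 1e-3 AU/ms).
#' @return The matrix on log2 scale.
#' @export
to_log2 <- function(x, floor = 1e-3) {
  if (signal_scale(x) != "linear") abort("Matrix is already on log2 scale.")
  out <- mutate(x, value = log2(pmax(.data$value, floor)))
  attr(out, "transform") <- "log2"
  p <- attr(x, "params") %||% list()
  p$log2_floor <- floor
  attr(out, "params") <- p
  out
}

.check_grid <- function(raw, design) {
  need <- c("substrate_id", "chip_type", "patient_id", "sex", "tissue",
            "treatment", "replicate", "cycle", "exposure_ms", "intensity")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Raw table missing column(s): ", paste(missing, collapse = ", ")))
  }
  counts <- raw |>
    count(.data$substrate_id, .data$chip_type, .data$patient_id, .data$tissue,
          .data$treatment, .data$replicate)
  expected <- design$cycles_per_chip[counts$chip_type] *
    length(design$exposure_times)
  bad <- which(counts$n != expected)
  if (length(bad) > 0) {
    b <- counts[bad[1], ]
    abort(paste0("Incomplete cycle x exposure grid for (",
                 b$substrate_id, ", ", b$patient_id, ", ", b$tissue, ", ",
                 b$treatment, ", rep ", b$replicate, "): ",
                 b$n, " rows, expected ", expected[bad[1]]))
  }
  invisible(TRUE)
}

#' Apply a QC policy to a quantified matrix
#'
#' Handles cells whose flag is not `ok` according to `policy`:
#' `"mask_cell"` (default) sets their value to `NA`, `"drop_substrate"`
#' removes every row of any substrate with at least one flagged cell, and
#' `"keep"` leaves values untouched. A QC report (flag counts by category)
#' is attached as attribute `qc_report` and retrievable with [qc_report()].
#'
#' @param matrix A `quantified_signals` tibble.
#' @param policy One of `"mask_cell"`, `"drop_substrate"`, `"keep"`.
#' @return The filtered matrix with a `qc_report` attribute.
#' @export
qc_filter <- function(matrix, policy = c("mask_cell", "drop_substrate", "keep")) {
  if (is.character(policy) && length(policy) == 1 &&
      !policy %in% c("mask_cell", "drop_substrate", "keep")) {
    abort(paste0("Unknown QC policy: ", policy))
  }
  policy <- match.arg(policy)
  report <- matrix |>
    count(.data$qc_flag) |>
    pivot_wider(names_from = "qc_flag", values_from = "n")
  for (f in c("ok", "saturated", "low_signal", "high_cv")) {
    if (!f %in% names(report)) report[[f]] <- 0L
  }
  report <- select(report, "ok", "saturated", "low_signal", "high_cv")

  out <- switch(policy,
    keep = matrix,
    mask_cell = mutate(matrix, value = ifelse(.data$qc_flag == "ok",
                                              .data$value, NA_real_)),
    drop_substrate = {
      bad <- unique(matrix$substrate_id[matrix$qc_flag != "ok"])
      filter(matrix, !.data$substrate_id %in% bad)
    }
  )
  out <- new_quantified(out, signal_scale(matrix), attr(matrix, "params"),
                        attr(matrix, "design"))
  attr(out, "qc_report") <- list(policy = policy, counts = report)
  out
}

#' QC report attached by [qc_filter()]
#' @param x A matrix returned by [qc_filter()].
#' @return A list with `policy` and a one-row tibble `counts`.
#' @export
qc_report <- function(x) attr(x, "qc_report")

#' Write / read a quantified matrix as wide TSV
#'
#' Substrates in rows, one column per (patient, tissue, treatment) cell;
#' masked cells are `NA`. A header comment records the scale.
#' @param matrix A `quantified_signals` tibble.
#' @param path File path.
#' @param config_hash Optional hash string recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, config_hash = NULL) {
  wide <- matrix |>
    mutate(column = paste(.data$patient_id, .data$tissue, .data$treatment,
                          sep = "|")) |>
    pivot_wider(id_cols = c("substrate_id", "chip_type"),
                names_from = "column", values_from = "value") |>
    arrange(.data$chip_type, .data$substrate_id)
  hdr <- paste0("# kinomechip quantified matrix scale=", signal_scale(matrix),
                if (!is.null(config_hash)) paste0(" config_hash=", config_hash))
  writeLines(hdr, path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
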