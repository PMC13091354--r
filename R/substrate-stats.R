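#' Paired tumor-vs-adjacent log fold changes per substrate
#'
#' For every substrate, the per-patient log2 fold change between tumor and
#' adjacent tissue (`log2(tumor) - log2(adjacent)`) and its mean across
#' patients. Requires a log2-scale matrix restricted to a single treatment
#' (typically vehicle). Substrates whose signal is masked (`NA`) in a
#' patient lose that pair; `n_pairs` records the pairs actually used. Cells
#' with `|mean LFC|` at or above `threshold` are flagged (waterfall
#' candidates).
#'
#' @param matrix A log2-scale `quantified_signals` tibble with both tissues
#'   for every patient and exactly one treatment.
#' @param sex Optional `"M"`/`"F"` filter; default uses all patients.
#' @param threshold Flag threshold in log2 units (default 0.2).
#' @param tumor,adjacent Tissue labels of the pair (defaults `"tumor"`,
#'   `"adjacent"`).
#' @return A tibble of class `substrate_stats`: `substrate_id`, `chip_type`,
#'   `mean_lfc`, `n_pairs`, `flag`, and a list-column `per_pair_lfc` (named
#'   per-patient LFCs). Attributes: `threshold`, `contrast`.
#' @export
paired_lfc <- function(matrix, sex = NULL, threshold = 0.2,
                       tumor = "tumor", adjacent = "adjacent") {
  if (signal_scale(matrix) != "log2") {
    abort("`paired_lfc()` needs a log2-scale matrix; see `to_log2()`.")
  }
  m <- as_tibble(matrix)
  if (!is.null(sex)) m <- filter(m, .data$sex %in% .env$sex)
  if (dplyr::n_distinct(m$treatment) != 1) {
    abort("Matrix must contain exactly one treatment; filter before pairing.")
  }
  if (!all(c(tumor, adjacent) %in% m$tissue)) {
    abort("Both tissues of the pair must be present.")
  }
  have <- m |>
    distinct(.data$patient_id, .data$tissue) |>
    count(.data$patient_id)
  unpaired <- have$patient_id[have$n < 2]
  if (length(unpaired) > 0) {
    abort(paste0("Patient without both tissues: ", unpaired[1]))
  }
  pairs <- m |>
    select("substrate_id", "chip_type", "patient_id", "tissue", "value") |>
    pivot_wider(names_from = "tissue", values_from = "value") |>
    mutate(lfc = .data[[tumor]] - .data[[adjacent]]) |>
    filter(!is.na(.data$lfc))
  .summarise_lfc(pairs, pair_id = "patient_id", threshold,
                 contrast = paste0(tumor, "-vs-", adjacent))
}

#' Drug-vs-vehicle log fold changes per substrate
#'
#' Per substrate and per sample (patient x tissue), the log2 fold change
#' `log2(drug) - log2(vehicle)`, then the mean across samples, with the same
#' flagging machinery as [paired_lfc()].
#'
#' @param matrix A log2-scale `quantified_signals` tibble containing both
#'   treatment labels.
#' @param vehicle_label,drug_label Treatment labels contrasted.
#' @param threshold Flag threshold in log2 units (default 0.2).
#' @return A `substrate_stats` tibble (see [paired_lfc()]); the pairing unit
#'   is the sample, recorded as `patient_id|tissue`.
#' @export
treatment_lfc <- function(matrix, vehicle_label, drug_label, threshold = 0.2) {
  if (signal_scale(matrix) != "log2") {
    abort("`treatment_lfc()` needs a log2-scale matrix; see `to_log2()`.")
  }
  m <- as_tibble(matrix)
  for (lab in c(vehicle_label, drug_label)) {
    if (!lab %in% m$treatment) abort(paste0("Treatment label absent: ", lab))
  }
  pairs <- m |>
    filter(.data$treatment %in% c(vehicle_label, drug_label)) |>
    mutate(sample = paste(.data$patient_id, .data$tissue, sep = "|")) |>
    select("substrate_id", "chip_type", "sample", "treatment", "value") |>
    pivot_wider(names_from = "treatment", values_from = "value") |>
    mutate(lfc = .data[[drug_label]] - .data[[vehicle_label]]) |>
    filter(!is.na(.data$lfc))
  .summarise_lfc(pairs, pair_id = "sample", threshold,
                 contrast = paste0(drug_label, "-vs-", vehicle_label))
}

.summarise_lfc <- function(pairs, pair_id, threshold, contrast) {
  out <- pairs |>
    group_by(.data$substrate_id, .data$chip_type) |>
    summarise(
      mean_lfc = mean(.data$lfc),
      n_pairs = n(),
      per_pair_lfc = list(setNames(.data$lfc, .data[[pair_id]])),
      .groups = "drop"
    ) |>
    mutate(flag = abs(.data$mean_lfc) >= threshold) |>
    arrange(.data$substrate_id)
  attr(out, "threshold") <- threshold
  attr(out, "contrast") <- contrast
  class(out) <- unique(c("substrate_stats", class(out)))
  out
}

#' Flagged substrates in waterfall order
#'
#' Substrates whose `|mean LFC|` meets the threshold (inclusive), sorted by
#' signed LFC descending — the order of a waterfall plot.
#'
#' @param stats A `substrate_stats` tibble.
#' @param threshold Flag threshold in log2 units; defaults to the threshold
#'   the stats were built with (0.2 if unset).
#' @return The flagged subset, sorted by `mean_lfc` descending.
#' @export
flag_substrates <- function(stats, threshold = attr(stats, "threshold") %||% 0.2) {
  if (threshold <= 0) abort("`threshold` must be > 0.")
  stats |>
    filter(abs(.data$mean_lfc) >= threshold) |>
    arrange(desc(.data$mean_lfc))
}

#' Heat-map-ready matrix with optional row scaling and clustering
#'
#' Reshapes a quantified matrix to substrates x sample-condition columns,
#' optionally z-scores each row (mean 0, sd 1), and orders rows by
#' average-linkage hierarchical clustering on correlation distance
#' (`1 - r`). Constant rows, whose z-score and correlation are undefined,
#' are emitted as zeros with a warning and placed at maximal distance from
#' every other row.
#'
#' @param matrix A `quantified_signals` tibble.
#' @param row_scaling `"none"` or `"zscore"`.
#' @param cluster Order rows by clustering (default `TRUE`); `FALSE` keeps
#'   input order.
#' @return A wide tibble (first columns `substrate_id`, `chip_type`), rows in
#'   display order; attributes `row_order`, `row_scaling`, `constant_rows`.
#' @export
heatmap_matrix <- function(matrix, row_scaling = c("none", "zscore"),
                           cluster = TRUE) {
  row_scaling <- match.arg(row_scaling)
  wide <- matrix |>
    as_tibble() |>
    mutate(column = paste(.data$patient_id, .data$tissue, .data$treatment,
                          sep = "|")) |>
    pivot_wider(id_cols = c("substrate_id", "chip_type"),
                names_from = "column", values_from = "value") |>
    arrange(.data$chip_type, .data$substrate_id)
  vals <- as.matrix(wide[, -(1:2)])
  rownames(vals) <- wide$substrate_id

  row_sd <- apply(vals, 1, sd)
  constant <- !is.na(row_sd) & row_sd == 0
  if (row_scaling == "zscore") {
    if (any(constant)) {
      warn(paste0(sum(constant), " constant row(s) z-scored as zeros."))
    }
    mu <- rowMeans(vals)
    vals <- (vals - mu) / ifelse(constant, 1, row_sd)
    vals[constant, ] <- 0
  }

  ord <- seq_len(nrow(vals))
  if (cluster && nrow(vals) >= 3) {
    cr <- suppressWarnings(cor(t(vals)))
    cr[is.na(cr)] <- 0
    d <- 1 - cr
    diag(d) <- 0
    ord <- hclust(as.dist(d), method = "average")$order
  }
  out <- wide[ord, ]
  if (row_scaling == "zscore") {
    out[, -(1:2)] <- as_tibble(vals[ord, , drop = FALSE])
  }
  attr(out, "row_order") <- wide$substrate_id[ord]
  attr(out, "row_scaling") <- row_scaling
  attr(out, "constant_rows") <- wide$substrate_id[constant]
  out
}
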