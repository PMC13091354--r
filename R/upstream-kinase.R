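# Mapped & measured substrate LFCs for one kinase, plus the same-chip panel.
# Sampling is always within chip type: PTK and STK runs are separate chips,
# so a PTK kinase is compared against the measured PTK panel only.
.kinase_panel <- function(stats, map, kinase) {
  mapped <- map$edges$substrate_id[map$edges$kinase_id == kinase]
  obs <- filter(as_tibble(stats), .data$substrate_id %in% mapped)
  if (nrow(obs) == 0) {
    abort(paste0("Kinase has no measured substrates: ", kinase),
          class = "kinomechip_unscorable")
  }
  chip <- names(sort(table(obs$chip_type), decreasing = TRUE))[1]
  obs <- filter(obs, .data$chip_type == chip)
  panel <- filter(as_tibble(stats), .data$chip_type == chip) |>
    arrange(.data$substrate_id)
  list(obs = arrange(obs, .data$substrate_id), panel = panel, chip = chip)
}

#' Kinase-level statistic: mean LFC of mapped substrates
#'
#' The observed activity-change statistic of a kinase: the arithmetic mean of
#' the per-substrate mean log2 fold changes over the kinase's mapped and
#' measured substrates (restricted to the kinase's chip type).
#'
#' @param stats A `substrate_stats` tibble ([paired_lfc()], [treatment_lfc()]).
#' @param map A [kinase_substrate_map()].
#' @param kinase Kinase id.
#' @return The mean LFC in log2 units.
#' @export
kinase_statistic <- function(stats, map, kinase) {
  kp <- .kinase_panel(stats, map, kinase)
  mean(kp$obs$mean_lfc)
}

#' Sampling-null Z-score for one kinase
#'
#' Standardises the observed kinase statistic against a random-sampling null:
#' `n_iter` subsets of the same size as the kinase's mapped substrate set are
#' drawn uniformly without replacement from the measured panel of the same
#' chip type, the mean-LFC statistic is computed on each, and
#' `z = (observed - null mean) / null sd` (sample SD of the draws).
#' Deterministic given `seed`.
#'
#' @param stats A `substrate_stats` tibble.
#' @param map A [kinase_substrate_map()].
#' @param kinase Kinase id.
#' @param n_iter Number of null draws (default 2000).
#' @param seed Integer seed.
#' @param min_substrates Minimum mapped-and-measured substrates required
#'   (default 3).
#' @return A one-row tibble: `kinase_id`, `m`, `stat`, `z`, `null_mean`,
#'   `null_sd`.
#' @export
sampling_z <- function(stats, map, kinase, n_iter = 2000, seed = 1,
                       min_substrates = 3) {
  kp <- .kinase_panel(stats, map, kinase)
  m <- nrow(kp$obs)
  if (m < min_substrates) {
    abort(paste0("Kinase ", kinase, " has m = ", m,
                 " < min_substrates = ", min_substrates),
          class = "kinomechip_unscorable")
  }
  panel <- kp$panel$mean_lfc
  if (length(panel) <= m) {
    abort("Measured panel must be larger than the mapped substrate set.",
          class = "kinomechip_degenerate")
  }
  obs <- mean(kp$obs$mean_lfc)
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_iter),
           function(i) mean(panel[sample.int(length(panel), m)]),
           numeric(1))
  })
  mu <- mean(draws)
  s <- sd(draws)
  if (s == 0) {
    abort(paste0("Zero-variance sampling null for ", kinase,
                 " (panel LFCs degenerate); z undefined."),
          class = "kinomechip_degenerate")
  }
  tibble(kinase_id = kinase, m = m, stat = obs,
         z = (obs - mu) / s, null_mean = mu, null_sd = s)
}

#' Exact Z-score by exhaustive subset enumeration
#'
#' Exact counterpart of [sampling_z()]: the null mean and SD are computed by
#' enumerating every size-`m` subset of the measured panel (population SD
#' over all `choose(n, m)` subset means). Only feasible when
#' `choose(n, m) <= 200000`.
#'
#' @inheritParams sampling_z
#' @return A one-row tibble: `kinase_id`, `m`, `stat`, `z`, `null_mean`,
#'   `null_sd`, `n_subsets`.
#' @export
exhaustive_z <- function(stats, map, kinase, min_substrates = 3) {
  kp <- .kinase_panel(stats, map, kinase)
  m <- nrow(kp$obs)
  if (m < min_substrates) {
    abort(paste0("Kinase ", kinase, " has m < min_substrates."),
          class = "kinomechip_unscorable")
  }
  panel <- kp$panel$mean_lfc
  n <- length(panel)
  if (n <= m) {
    abort("Panel size must exceed m; null degenerate.",
          class = "kinomechip_degenerate")
  }
  n_sub <- choose(n, m)
  if (n_sub > 200000) {
    abort(paste0("choose(", n, ", ", m, ") = ", n_sub,
                 " exceeds the 200000 enumeration bound."),
          class = "kinomechip_size")
  }
  means <- combn(panel, m, mean)
  mu <- mean(means)
  s <- sqrt(mean((means - mu)^2))
  if (s == 0) {
    abort("Zero-variance exhaustive null; z undefined.",
          class = "kinomechip_degenerate")
  }
  obs <- mean(kp$obs$mean_lfc)
  tibble(kinase_id = kinase, m = m, stat = obs, z = (obs - mu) / s,
         null_mean = mu, null_sd = s, n_subsets = n_sub)
}

# pairs x substrates LFC matrix for one kinase (NA where a pair is missing)
.pair_matrix <- function(obs) {
  pair_names <- sort(unique(unlist(lapply(obs$per_pair_lfc, names))))
  L <- matrix(NA_real_, nrow = length(pair_names), ncol = nrow(obs),
              dimnames = list(pair_names, obs$substrate_id))
  for (j in seq_len(nrow(obs))) {
    v <- obs$per_pair_lfc[[j]]
    L[names(v), j] <- v
  }
  L
}

#' Two-component upstream kinase ranking
#'
#' Ranks kinases by a documented two-component score combining specificity
#' and significance, in the spirit of hierarchical upstream-kinase rating
#' tools (the construction is this package's own and is not expected to
#' match any proprietary implementation numerically):
#'
#' * `specificity_z` — the observed mean-LFC statistic standardised against
#'   a null of random same-size substrate sets drawn from the measured panel
#'   of the same chip type (is the signal specific to *these* substrates?).
#' * `significance_z` — the statistic standardised against a sign-flip null
#'   that randomly negates each pair's LFCs (consistently across substrates,
#'   matching the paired design; is the signal distinguishable from noise?).
#' * `final_score = sign(stat) * mean(|specificity_z|, |significance_z|)`.
#'
#' Kinases are ranked by `|final_score|` (dense ranks); ties break by larger
#' substrate count `m`, then lexicographic kinase id. Degenerate nulls
#' (zero SD, e.g. all LFCs zero) contribute a component z of 0.
#'
#' @param stats A `substrate_stats` tibble with the `per_pair_lfc`
#'   list-column.
#' @param map A [kinase_substrate_map()].
#' @param n_perm Null draws for both components (default 500; values below
#'   100 trigger a warning).
#' @param seed Integer seed; each kinase uses a sub-seed derived from it, so
#'   results do not depend on substrate or kinase row order.
#' @param min_substrates Minimum mapped-and-measured substrates (default 3).
#' @return A tibble of class `uka_result`, one row per scored kinase:
#'   `kinase_id`, `family_group`, `m`, `stat`, `specificity_z`,
#'   `significance_z`, `final_score`, `rank`, sorted by rank.
#' @export
uka_rank <- function(stats, map, n_perm = 500, seed = 1, min_substrates = 3) {
  if (n_perm < 100) {
    warn(paste0("n_perm = ", n_perm, " is below 100; z estimates will be noisy."))
  }
  if (!"per_pair_lfc" %in% names(stats)) {
    abort("`stats` must carry the per_pair_lfc list-column (see paired_lfc()).")
  }
  kin_ids <- sort(unique(map$edges$kinase_id))
  measured <- unique(as_tibble(stats)$substrate_id)
  rows <- purrr::map(seq_along(kin_ids), function(i) {
    kid <- kin_ids[i]
    mapped <- map$edges$substrate_id[map$edges$kinase_id == kid]
    if (length(intersect(mapped, measured)) < min_substrates) return(NULL)
    kp <- .kinase_panel(stats, map, kid)
    m <- nrow(kp$obs)
    if (m < min_substrates) return(NULL)
    panel <- kp$panel$mean_lfc
    if (length(panel) <= m) return(NULL)
    obs <- mean(kp$obs$mean_lfc)

    L <- .pair_matrix(kp$obs)
    L0 <- ifelse(is.na(L), 0, L)
    n_per_col <- colSums(!is.na(L))

    sub_seed <- (as.integer(seed) + i) %% .Machine$integer.max
    zz <- withr::with_seed(sub_seed, {
      spec_draws <- vapply(seq_len(n_perm),
                           function(j) mean(panel[sample.int(length(panel), m)]),
                           numeric(1))
      S <- matrix(sample(c(-1, 1), nrow(L) * n_perm, replace = TRUE),
                  nrow = nrow(L))
      sig_draws <- colMeans(crossprod(L0, S) / n_per_col)
      list(spec = spec_draws, sig = sig_draws)
    })
    z_of <- function(draws) {
      s <- sd(draws)
      if (is.na(s) || s == 0) 0 else (obs - mean(draws)) / s
    }
    tibble(kinase_id = kid, m = m, stat = obs,
           specificity_z = z_of(zz$spec), significance_z = z_of(zz$sig))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("No scorable kinases (check min_substrates).")
  out <- out |>
    left_join(map$kinases, by = "kinase_id") |>
    mutate(final_score = sign(.data$stat) *
             (abs(.data$specificity_z) + abs(.data$significance_z)) / 2) |>
    arrange(desc(abs(.data$final_score)), desc(.data$m), .data$kinase_id) |>
    mutate(rank = dplyr::row_number()) |>
    select("kinase_id", "family_group", "m", "stat", "specificity_z",
           "significance_z", "final_score", "rank")
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "min_substrates") <- min_substrates
  class(out) <- unique(c("uka_result", class(out)))
  out
}

#' Sampling-null Z-scores for every scorable kinase
#'
#' Applies [sampling_z()] across the annotation and returns a waterfall-ready
#' table ranked by signed Z (descending).
#'
#' @inheritParams uka_rank
#' @param n_iter Null draws per kinase (default 2000).
#' @return A tibble of class `krsa_result`: `kinase_id`, `family_group`, `m`,
#'   `stat`, `z`, `rank`.
#' @export
z_score_kinases <- function(stats, map, n_iter = 2000, seed = 1,
                            min_substrates = 3) {
  kin_ids <- sort(unique(map$edges$kinase_id))
  measured <- unique(as_tibble(stats)$substrate_id)
  rows <- purrr::map(seq_along(kin_ids), function(i) {
    kid <- kin_ids[i]
    mapped <- map$edges$substrate_id[map$edges$kinase_id == kid]
    if (length(intersect(mapped, measured)) < min_substrates) return(NULL)
    sub_seed <- (as.integer(seed) + i) %% .Machine$integer.max
    tryCatch(
      sampling_z(stats, map, kid, n_iter = n_iter, seed = sub_seed,
                 min_substrates = min_substrates),
      kinomechip_degenerate = function(e) NULL,
      kinomechip_unscorable = function(e) NULL
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("No scorable kinases (check min_substrates).")
  out <- out |>
    left_join(map$kinases, by = "kinase_id") |>
    arrange(desc(.data$z)) |>
    mutate(rank = dplyr::row_number()) |>
    select("kinase_id", "family_group", "m", "stat", "z", "rank")
  class(out) <- unique(c("krsa_result", class(out)))
  out
}

#' Export kinase scores as a kinome-tree annotation table
#'
#' One row per scored kinase in the plain-TSV layout common kinome-tree
#' renderers accept: `kinase_id`, `family_group` (branch), `activity` (node
#' color; the signed kinase statistic) and `significance` (node size;
#' `|final_score|` for UKA results, `|z|` for Z-score results). Kinases with
#' no family label are assigned `"Other"` with a warning.
#'
#' @param scores A `uka_result` or `krsa_result` tibble.
#' @param map Optional [kinase_substrate_map()] used to fill family labels.
#' @return A tibble with the four documented columns.
#' @export
kinome_tree_export <- function(scores, map = NULL) {
  fam <- scores$family_group
  if (!is.null(map)) {
    idx <- match(scores$kinase_id, map$kinases$kinase_id)
    fam <- dplyr::coalesce(fam, map$kinases$family_group[idx])
  }
  if (anyNA(fam)) {
    warn(paste0(sum(is.na(fam)), " kinase(s) without family label assigned 'Other'."))
    fam[is.na(fam)] <- "Other"
  }
  tibble(
    kinase_id = scores$kinase_id,
    family_group = fam,
    activity = scores$stat,
    significance = if ("final_score" %in% names(scores)) {
      abs(scores$final_score)
    } else abs(scores$z)
  )
}
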