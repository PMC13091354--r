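#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the long per-observation table of
#' a result, `glance()` a one-row (or per-group) summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name kinomechip-tidiers
NULL

#' @rdname kinomechip-tidiers
#' @export
tidy.substrate_stats <- function(x, ...) {
  out <- as_tibble(x)
  select(out, "substrate_id", "chip_type", "mean_lfc", "n_pairs", "flag")
}

#' @rdname kinomechip-tidiers
#' @export
glance.substrate_stats <- function(x, ...) {
  tibble(
    contrast = attr(x, "contrast"),
    threshold = attr(x, "threshold"),
    n_substrates = nrow(x),
    n_flagged = sum(x$flag)
  )
}

#' @rdname kinomechip-tidiers
#' @export
tidy.uka_result <- function(x, ...) as_tibble(x)

#' @rdname kinomechip-tidiers
#' @export
glance.uka_result <- function(x, ...) {
  tibble(
    n_kinases = nrow(x),
    n_perm = attr(x, "n_perm"),
    min_substrates = attr(x, "min_substrates"),
    top_kinase = x$kinase_id[x$rank == 1][1]
  )
}

#' @rdname kinomechip-tidiers
#' @export
tidy.krsa_result <- function(x, ...) as_tibble(x)

#' @rdname kinomechip-tidiers
#' @export
glance.krsa_result <- function(x, ...) {
  tibble(n_kinases = nrow(x), top_kinase = x$kinase_id[x$rank == 1][1])
}

#' @rdname kinomechip-tidiers
#' @export
tidy.permed_report <- function(x, ...) {
  mutate(as_tibble(x), kinase_id = attr(x, "kinase"), .before = 1)
}

#' @rdname kinomechip-tidiers
#' @export
glance.permed_report <- function(x, ...) {
  tibble(
    kinase_id = attr(x, "kinase"),
    contrast = attr(x, "contrast"),
    score = attr(x, "score"),
    n_substrates = attr(x, "n_substrates"),
    n_excluded = nrow(attr(x, "excluded"))
  )
}

#' @rdname kinomechip-tidiers
#' @export
tidy.trial_report <- function(x, ...) as_tibble(x$scores)

#' @rdname kinomechip-tidiers
#' @export
glance.trial_report <- function(x, ...) as_tibble(x$summary)
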