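#' Kinase-substrate annotation map
#'
#' A weighted bipartite map linking peptide substrates on the PTK/STK chips to
#' the upstream kinases able to phosphorylate them, with kinome family labels
#' (TK, TKL, STE, CK1, AGC, CAMK, CMGC, Other) on the kinase side. This is the
#' annotation that upstream-kinase deconvolution and PerMed scoring consume.
#'
#' @param kinases Data frame with columns `kinase_id`, `family_group`.
#' @param substrates Data frame with columns `substrate_id`, `chip_type`.
#' @param edges Data frame with columns `kinase_id`, `substrate_id`, `weight`
#'   (catalytic efficiency in (0, 1]).
#' @return A validated object of class `kinase_substrate_map`: a list of the
#'   three tibbles, each sorted by id.
#' @export
kinase_substrate_map <- function(kinases, substrates, edges) {
  kinases <- arrange(as_tibble(kinases), .data$kinase_id)
  substrates <- arrange(as_tibble(substrates), .data$substrate_id)
  edges <- arrange(as_tibble(edges), .data$kinase_id, .data$substrate_id)
  stopifnot(
    all(c("kinase_id", "family_group") %in% names(kinases)),
    all(c("substrate_id", "chip_type") %in% names(substrates)),
    all(c("kinase_id", "substrate_id", "weight") %in% names(edges))
  )
  if (anyDuplicated(kinases$kinase_id)) abort("Duplicate kinase_id in kinase table.")
  if (anyDuplicated(substrates$substrate_id)) abort("Duplicate substrate_id in substrate table.")
  fams <- c("TK", "TKL", "STE", "CK1", "AGC", "CAMK", "CMGC", "Other")
  if (!all(kinases$family_group %in% fams)) {
    abort(paste0("Unknown family_group; allowed: ", paste(fams, collapse = ", ")))
  }
  dup <- duplicated(edges[c("kinase_id", "substrate_id")])
  if (any(dup)) {
    abort(paste0("Duplicate (kinase, substrate) edge(s): ",
                 paste(utils::head(paste(edges$kinase_id[dup], edges$substrate_id[dup],
                                         sep = "/"), 5), collapse = ", ")))
  }
  if (!all(edges$kinase_id %in% kinases$kinase_id)) {
    bad <- setdiff(edges$kinase_id, kinases$kinase_id)
    abort(paste0("Edge references unknown kinase: ", bad[1]))
  }
  if (!all(edges$substrate_id %in% substrates$substrate_id)) {
    bad <- setdiff(edges$substrate_id, substrates$substrate_id)
    abort(paste0("Edge references unknown substrate: ", bad[1]))
  }
  if (!all(edges$weight > 0 & edges$weight <= 1)) {
    abort("Edge weights must lie in (0, 1].")
  }
  orphan <- setdiff(substrates$substrate_id, edges$substrate_id)
  if (length(orphan) > 0) {
    abort(paste0("Substrate(s) without any kinase edge: ", orphan[1]))
  }
  structure(list(kinases = kinases, substrates = substrates, edges = edges),
            class = "kinase_substrate_map")
}

#' @export
print.kinase_substrate_map <- function(x, ...) {
  cat("<kinase_substrate_map>", nrow(x$kinases), "kinases,",
      nrow(x$substrates), "substrates,", nrow(x$edges), "edges\n")
  chip <- table(x$substrates$chip_type)
  cat("  substrates per chip:", paste(names(chip), chip, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Canonical kinases always present in the default fixture, with their
# kinome branch and the chip their substrates live on.
.named_kinases <- function() {
  tibble(
    kinase_id = c("ABL1", "ABL2", "INSR", "SYK", "DDR1", "FRK", "SRC",
                  "AKT1", "AKT2", "ERK1", "GSK3", "AMPKA1", "AURA"),
    family_group = c(rep("TK", 7), "AGC", "AGC", "CMGC", "CMGC", "CAMK", "Other"),
    chip = c(rep("PTK", 7), rep("STK", 6)),
    min_substrates = c(12L, rep(6L, 12))
  )
}

#' Build the default kinase-substrate annotation fixture
#'
#' Generates a structurally realistic annotation for the standard dual-chip
#' layout: 196 PTK and 144 STK substrates (340 total) and a kinase list of
#' 500+ kinases spanning the eight kinome branches. PTK substrates are
#' annotated to TK/TKL kinases and STK substrates to the serine/threonine
#' branches. Each substrate's kinase degree is drawn as
#' `1 + Binomial(14, 0.36)` (support 1..15, mean about 6); catalytic weights
#' are Uniform(0.3, 1). Canonical kinases (ABL1, ABL2, INSR, SYK, DDR1, FRK,
#' SRC, AKT1, AKT2, ERK1, GSK3, AMPKA1, AURA) are guaranteed present with
#' realistic substrate sets (ABL1 maps to at least 10 PTK substrates).
#' Kinases that end up with no annotated substrate are dropped, so every
#' listed kinase has at least one edge. Fully deterministic given `seed`.
#'
#' @param seed Non-negative integer seed.
#' @param design An [assay_design()]; sets substrate counts per chip.
#' @return A [kinase_substrate_map()].
#' @examples
#' map <- build_default_annotation(seed = 0)
#' nrow(map$substrates) # 340
#' @export
build_default_annotation <- function(seed = 0, design = assay_design()) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  withr::with_seed(as.integer(seed), .build_annotation_impl(design))
}

.build_annotation_impl <- function(design) {
  named <- .named_kinases()
  # synthetic kinome roster: counts per branch roughly proportional to the
  # human kinome, totalling 620 with the named kinases included
  branch_n <- c(TK = 110, TKL = 50, STE = 55, CK1 = 15, AGC = 75,
                CAMK = 90, CMGC = 75, Other = 150)
  synth <- purrr::map2(names(branch_n), branch_n, function(fam, n) {
    n_named <- sum(named$family_group == fam)
    tibble(
      kinase_id = sprintf("KIN_%s_%03d", fam, seq_len(n - n_named)),
      family_group = fam
    )
  })
  kinases <- bind_rows(select(named, "kinase_id", "family_group"), bind_rows(synth))

  substrates <- bind_rows(lapply(design$chip_types, function(ct) {
    tibble(
      substrate_id = sprintf("%s_%03d", ct, seq_len(design$substrates_per_chip[[ct]])),
      chip_type = ct
    )
  }))

  ptk_pool <- kinases$kinase_id[kinases$family_group %in% c("TK", "TKL")]
  stk_pool <- kinases$kinase_id[!kinases$family_group %in% c("TK", "TKL")]

  edges <- purrr::pmap(substrates, function(substrate_id, chip_type) {
    pool <- if (chip_type == "PTK") ptk_pool else stk_pool
    deg <- 1L + stats::rbinom(1L, 14L, 0.36)
    tibble(kinase_id = sample(pool, deg), substrate_id = substrate_id)
  })
  edges <- bind_rows(edges)

  # guarantee canonical kinases carry realistic substrate sets on their chip
  for (i in seq_len(nrow(named))) {
    kid <- named$kinase_id[i]
    chip <- named$chip[i]
    have <- edges$substrate_id[edges$kinase_id == kid]
    chip_subs <- substrates$substrate_id[substrates$chip_type == chip]
    # scaled-down layouts cannot host the full canonical sets
    want <- min(named$min_substrates[i], length(chip_subs))
    have <- intersect(have, chip_subs)
    need <- want - length(have)
    if (need > 0) {
      new <- sample(setdiff(chip_subs, have), need)
      edges <- bind_rows(edges, tibble(kinase_id = kid, substrate_id = new))
    }
  }
  edges <- distinct(edges, .data$kinase_id, .data$substrate_id)
  edges$weight <- stats::runif(nrow(edges), 0.3, 1)

  kinases <- filter(kinases, .data$kinase_id %in% edges$kinase_id)
  kinase_substrate_map(kinases, substrates, edges)
}

#' Write an annotation map to a 5-column TSV
#'
#' One row per edge: `kinase_id`, `family_group`, `substrate_id`, `chip_type`,
#' `weight`. The inverse of [read_annotation()].
#'
#' @param map A [kinase_substrate_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(map, path) {
  flat <- map$edges |>
    left_join(map$kinases, by = "kinase_id") |>
    left_join(map$substrates, by = "substrate_id") |>
    select("kinase_id", "family_group", "substrate_id", "chip_type", "weight") |>
    arrange(.data$kinase_id, .data$substrate_id)
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Read an annotation map from a 5-column TSV
#'
#' @param path Path to a TSV with columns `kinase_id`, `family_group`,
#'   `substrate_id`, `chip_type`, `weight` (one row per edge).
#' @return A validated [kinase_substrate_map()].
#' @export
read_annotation <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    kinase_id = readr::col_character(),
    family_group = readr::col_character(),
    substrate_id = readr::col_character(),
    chip_type = readr::col_character(),
    weight = readr::col_double()
  ), comment = "#")
  need <- c("kinase_id", "family_group", "substrate_id", "chip_type", "weight")
  missing <- setdiff(need, names(flat))
  if (length(missing) > 0) {
    abort(paste0("Annotation file missing column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- duplicated(flat[c("kinase_id", "substrate_id")])
  if (any(dup)) {
    # +1 for the header line
    abort(paste0("Duplicate edge at line(s): ",
                 paste(which(dup) + 1L, collapse = ", ")))
  }
  kin <- distinct(flat, .data$kinase_id, .data$family_group)
  if (anyDuplicated(kin$kinase_id)) {
    abort("Inconsistent family_group for a kinase across rows.")
  }
  sub <- distinct(flat, .data$substrate_id, .data$chip_type)
  if (anyDuplicated(sub$substrate_id)) {
    abort("Inconsistent chip_type for a substrate across rows.")
  }
  kinase_substrate_map(kin, sub, select(flat, "kinase_id", "substrate_id", "weight"))
}
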