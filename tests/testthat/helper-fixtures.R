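# Shared fixtures: small designs and toy annotation maps built in code.

small_design <- function(ptk = 12L, stk = 8L, cycles_ptk = 20L, cycles_stk = 24L) {
  assay_design(
    substrates_per_chip = c(PTK = ptk, STK = stk),
    cycles_per_chip = c(PTK = cycles_ptk, STK = cycles_stk)
  )
}

small_cohort <- function(n_rep = 2L, pooled = FALSE,
                         tissues = c("tumor", "adjacent")) {
  cohort_design(
    patients = tibble::tibble(
      patient_id = c("P1", "P2", "P3"),
      sex = c("M", "M", "F")
    ),
    tissues = tissues,
    technical_replicates = n_rep,
    pooled = pooled
  )
}

# One kinase, one exclusively mapped substrate on the PTK chip.
toy_map_1k1s <- function(weight = 0.5) {
  kinase_substrate_map(
    kinases = tibble::tibble(kinase_id = "KA", family_group = "TK"),
    substrates = tibble::tibble(substrate_id = "PTK_001", chip_type = "PTK"),
    edges = tibble::tibble(kinase_id = "KA", substrate_id = "PTK_001",
                           weight = weight)
  )
}

# n_sub PTK substrates all exclusively mapped to one kinase.
toy_map_exclusive <- function(n_sub = 10, kinase = "KA") {
  subs <- sprintf("PTK_%03d", seq_len(n_sub))
  kinase_substrate_map(
    kinases = tibble::tibble(kinase_id = kinase, family_group = "TK"),
    substrates = tibble::tibble(substrate_id = subs, chip_type = "PTK"),
    edges = tibble::tibble(kinase_id = kinase, substrate_id = subs,
                           weight = runif(n_sub, 0.3, 1))
  )
}

noiseless <- function() list(spot_cv = 0, replicate_cv = 0, background_sd = 0)

toy_truth <- function(map, baselines = NULL, rates = NULL, ic50 = NULL,
                      noise = noiseless(), multipliers = NULL,
                      non_responders = NULL) {
  ground_truth(
    baseline_activity = baselines %||% tibble::tibble(
      kinase_id = map$kinases$kinase_id,
      baseline = seq(2, 4, length.out = nrow(map$kinases))
    ),
    condition_multipliers = multipliers,
    drug_ic50 = ic50,
    kinetic_rate = rates %||% tibble::tibble(
      substrate_id = map$substrates$substrate_id,
      rate = seq(0.03, 0.09, length.out = nrow(map$substrates))
    ),
    noise = noise,
    non_responders = non_responders
  )
}

single_drug_panel <- function(conc = 50, ic50_drug = "drugX",
                              target = "KA") {
  drug_panel(tibble::tibble(drug_id = ic50_drug, target_kinase = target,
                            concentration_nM = conc))
}

# Quantified matrix built directly from per-cell values.
mk_matrix <- function(df, transform = "linear") {
  df <- tibble::as_tibble(df)
  if (!"chip_type" %in% names(df)) df$chip_type <- "PTK"
  if (!"patient_id" %in% names(df)) df$patient_id <- "P1"
  if (!"tissue" %in% names(df)) df$tissue <- "tumor"
  as_quantified(df, transform = transform)
}

# substrate_stats built directly from per-pair LFC vectors (named lists).
mk_stats <- function(substrate_id, per_pair, chip_type = "PTK",
                     threshold = 0.2) {
  df <- tibble::tibble(
    substrate_id = substrate_id,
    chip_type = rep_len(chip_type, length(substrate_id)),
    per_pair_lfc = per_pair
  )
  df$mean_lfc <- vapply(df$per_pair_lfc, mean, numeric(1))
  df$n_pairs <- vapply(df$per_pair_lfc, length, integer(1))
  df$flag <- abs(df$mean_lfc) >= threshold
  attr(df, "threshold") <- threshold
  attr(df, "contrast") <- "test"
  class(df) <- unique(c("substrate_stats", class(df)))
  df
}

# mk_stats from plain mean LFCs with a single synthetic pair each
mk_stats_means <- function(lfcs, ids = sprintf("PTK_%03d", seq_along(lfcs)),
                           chip_type = "PTK") {
  mk_stats(ids, lapply(lfcs, function(x) c(p1 = x)), chip_type = chip_type)
}
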