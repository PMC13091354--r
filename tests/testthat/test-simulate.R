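test_that("occupancy scaling follows the single-site model", {
  expect_identical(drug_scaling(10, 0, 50), 10)
  expect_identical(drug_scaling(10, 50, 50), 5)
  expect_identical(drug_scaling(8, 150, 50), 2)
  # monotone non-increasing in concentration
  conc <- seq(0, 1000, by = 50)
  act <- drug_scaling(rep(10, length(conc)), conc, 75)
  expect_true(all(diff(act) < 0))
  expect_error(drug_scaling(10, 10, 0), "ic50")
  expect_error(drug_scaling(10, -1, 10), "concentration")
})

test_that("noiseless intensities equal the closed-form kinetic curve", {
  design <- small_design(ptk = 1L, stk = 1L)
  map <- kinase_substrate_map(
    tibble::tibble(kinase_id = c("KA", "KB"), family_group = c("TK", "AGC")),
    tibble::tibble(substrate_id = c("PTK_001", "STK_001"),
                   chip_type = c("PTK", "STK")),
    tibble::tibble(kinase_id = c("KA", "KB"),
                   substrate_id = c("PTK_001", "STK_001"),
                   weight = c(0.5, 0.8))
  )
  truth <- toy_truth(map,
                     baselines = tibble::tibble(kinase_id = c("KA", "KB"),
                                                baseline = c(4, 3)),
                     rates = tibble::tibble(substrate_id = c("PTK_001", "STK_001"),
                                            rate = c(0.05, 0.08)))
  cohort <- cohort_design(patients = tibble::tibble(patient_id = "P1", sex = "M"),
                          tissues = "tumor", technical_replicates = 1)
  panel <- single_drug_panel(conc = 10)
  raw <- simulate_signals(design, map, truth, cohort, panel, seed = 1)

  veh <- dplyr::filter(raw, treatment == "vehicle", substrate_id == "PTK_001")
  expected <- design$background_level +
    veh$exposure_ms * (0.5 * 4) * (1 - exp(-0.05 * veh$cycle))
  expect_equal(veh$intensity, expected, tolerance = 1e-12)
})

test_that("at conc = IC50 the noiseless signal rise is exactly halved", {
  design <- small_design(ptk = 1L, stk = 1L)
  map <- toy_map_1k1s(weight = 0.5)
  # add an STK substrate so the design grid stays satisfiable
  map <- kinase_substrate_map(
    dplyr::bind_rows(map$kinases,
                     tibble::tibble(kinase_id = "KB", family_group = "AGC")),
    dplyr::bind_rows(map$substrates,
                     tibble::tibble(substrate_id = "STK_001", chip_type = "STK")),
    dplyr::bind_rows(map$edges,
                     tibble::tibble(kinase_id = "KB", substrate_id = "STK_001",
                                    weight = 1))
  )
  truth <- toy_truth(map, ic50 = tibble::tibble(kinase_id = "KA",
                                                drug_id = "drugX",
                                                ic50_nM = 50))
  cohort <- cohort_design(patients = tibble::tibble(patient_id = "P1", sex = "M"),
                          tissues = "tumor", technical_replicates = 1)
  panel <- single_drug_panel(conc = 50)
  raw <- simulate_signals(design, map, truth, cohort, panel, seed = 1)
  bg <- design$background_level
  wide <- raw |>
    dplyr::filter(substrate_id == "PTK_001") |>
    tidyr::pivot_wider(id_cols = c(cycle, exposure_ms),
                       names_from = treatment, values_from = intensity)
  expect_equal(wide$drugX - bg, (wide$vehicle - bg) / 2, tolerance = 1e-12)
})

test_that("the emitted grid is complete with chip-specific cycle counts", {
  design <- small_design(ptk = 3L, stk = 2L, cycles_ptk = 94L, cycles_stk = 124L)
  map <- build_default_annotation(2, design)
  truth <- build_default_truth(map, seed = 2)
  cohort <- small_cohort(n_rep = 2L)
  panel <- drug_panel()
  raw <- simulate_signals(design, map, truth, cohort, panel, seed = 5)

  counts <- raw |>
    dplyr::count(chip_type, substrate_id, patient_id, tissue, treatment,
                 replicate)
  expect_true(all(counts$n[counts$chip_type == "PTK"] == 94 * 5))
  expect_true(all(counts$n[counts$chip_type == "STK"] == 124 * 5))
  n_samples <- 3 * 2 # patients x tissues
  n_treat <- 4
  expect_equal(nrow(raw),
               (3 * 94 + 2 * 124) * 5 * n_samples * n_treat * 2)
  # clipping bounds
  expect_true(all(raw$intensity >= 0 &
                    raw$intensity <= design$saturation_level))
})

test_that("simulation is deterministic given the seed", {
  design <- small_design(ptk = 4L, stk = 3L)
  map <- build_default_annotation(1, design)
  truth <- build_default_truth(map, seed = 1)
  cohort <- small_cohort()
  panel <- drug_panel()
  a <- simulate_signals(design, map, truth, cohort, panel, seed = 42)
  b <- simulate_signals(design, map, truth, cohort, panel, seed = 42)
  expect_identical(a$intensity, b$intensity)
  c <- simulate_signals(design, map, truth, cohort, panel, seed = 43)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("noiseless end-level of an exclusive substrate is dose-monotone", {
  design <- small_design(ptk = 1L, stk = 1L)
  map <- kinase_substrate_map(
    tibble::tibble(kinase_id = c("KA", "KB"), family_group = c("TK", "AGC")),
    tibble::tibble(substrate_id = c("PTK_001", "STK_001"),
                   chip_type = c("PTK", "STK")),
    tibble::tibble(kinase_id = c("KA", "KB"),
                   substrate_id = c("PTK_001", "STK_001"), weight = 1)
  )
  truth <- toy_truth(map, ic50 = tibble::tibble(
    kinase_id = rep("KA", 3), drug_id = c("d1", "d2", "d3"),
    ic50_nM = rep(40, 3)))
  panel <- drug_panel(tibble::tibble(
    drug_id = c("d1", "d2", "d3"), target_kinase = "KA",
    concentration_nM = c(10, 40, 400)))
  cohort <- cohort_design(patients = tibble::tibble(patient_id = "P1", sex = "M"),
                          tissues = "tumor", technical_replicates = 1)
  raw <- simulate_signals(design, map, truth, cohort, panel, seed = 1)
  q <- quantify(raw, design)
  v <- q |>
    dplyr::filter(substrate_id == "PTK_001") |>
    dplyr::arrange(factor(treatment, levels = c("vehicle", "d1", "d2", "d3"))) |>
    dplyr::pull(value)
  expect_true(all(diff(v) < 0))
})

test_that("simulation rejects inconsistent ids across inputs", {
  design <- small_design(ptk = 1L, stk = 1L)
  map <- kinase_substrate_map(
    tibble::tibble(kinase_id = c("KA", "KB"), family_group = c("TK", "AGC")),
    tibble::tibble(substrate_id = c("PTK_001", "STK_001"),
                   chip_type = c("PTK", "STK")),
    tibble::tibble(kinase_id = c("KA", "KB"),
                   substrate_id = c("PTK_001", "STK_001"), weight = 1)
  )
  truth <- toy_truth(map)
  cohort <- small_cohort()
  panel <- drug_panel(tibble::tibble(drug_id = "dX", target_kinase = "NOPE",
                                     concentration_nM = 10))
  expect_error(simulate_signals(design, map, truth, cohort, panel, seed = 1),
               "NOPE")
  # truth missing a substrate rate
  truth2 <- truth
  truth2$kinetic_rate <- truth2$kinetic_rate[1, ]
  expect_error(simulate_signals(design, map, truth2, cohort,
                                single_drug_panel(conc = 10), seed = 1),
               "kinetic rate")
})

test_that("pooled mode equals the per-sex mean of patient signals when noiseless", {
  design <- small_design(ptk = 4L, stk = 3L)
  map <- build_default_annotation(1, design)
  truth <- build_default_truth(map, seed = 1, noise = noiseless())
  panel <- drug_panel()
  per <- simulate_signals(design, map, truth, small_cohort(n_rep = 1L),
                          panel, seed = 2)
  pool <- simulate_signals(design, map, truth,
                           small_cohort(n_rep = 1L, pooled = TRUE),
                           panel, seed = 2)
  qp <- quantify(per, design)
  qq <- quantify(pool, design)
  per_mean <- qp |>
    dplyr::group_by(substrate_id, sex, tissue, treatment) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  joined <- dplyr::inner_join(
    per_mean, dplyr::select(tibble::as_tibble(qq), substrate_id, sex, tissue,
                            treatment, pooled = value),
    by = c("substrate_id", "sex", "tissue", "treatment"))
  expect_equal(joined$pooled, joined$value, tolerance = 1e-12)
})

test_that("noiseless analytic PerMed oracle behaves as the occupancy model dictates", {
  map <- toy_map_exclusive(n_sub = 2)
  # pad with STK substrate for validity is unnecessary here (no simulation)
  truth <- toy_truth(map, ic50 = tibble::tibble(kinase_id = "KA",
                                                drug_id = "drugX",
                                                ic50_nM = 50))
  panel <- single_drug_panel(conc = 50)
  expect_equal(truth_permed(map, truth, panel, "KA", "drugX"), -50)
  # no interaction -> 0
  truth0 <- toy_truth(map)
  expect_equal(truth_permed(map, truth0, panel, "KA", "drugX"), 0)
  # uniform weight doubling leaves the score unchanged
  map2 <- map
  map2$edges$weight <- pmin(map2$edges$weight * 2, 1)
  map2 <- kinase_substrate_map(map2$kinases, map2$substrates, map2$edges)
  expect_equal(truth_permed(map2, truth, panel, "KA", "drugX"),
               truth_permed(map, truth, panel, "KA", "drugX"))
  expect_error(truth_permed(map, truth, panel, "KB", "drugX"), "no mapped")
})

test_that("raw signal TSV round-trips", {
  design <- small_design(ptk = 2L, stk = 2L)
  map <- build_default_annotation(1, design)
  truth <- build_default_truth(map, seed = 1)
  raw <- simulate_signals(design, map, truth,
                          small_cohort(n_rep = 1L, tissues = "tumor"),
                          drug_panel(), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signals(raw, path)
  back <- read_signals(path)
  expect_equal(nrow(back), nrow(raw))
  expect_equal(back$intensity, raw$intensity, tolerance = 1e-12)
})
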