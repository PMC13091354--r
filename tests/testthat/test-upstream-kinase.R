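map_from_sets <- function(sets, panel_ids, chip = "PTK") {
  # sets: named list kinase -> substrate ids (subset of panel_ids)
  edges <- dplyr::bind_rows(lapply(names(sets), function(k) {
    tibble::tibble(kinase_id = k, substrate_id = sets[[k]], weight = 0.5)
  }))
  # pad unmapped panel substrates with a filler kinase so the map validates
  rest <- setdiff(panel_ids, edges$substrate_id)
  if (length(rest) > 0) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      kinase_id = "FILLER", substrate_id = rest, weight = 0.5))
  }
  kin <- tibble::tibble(kinase_id = unique(edges$kinase_id),
                        family_group = "TK")
  kinase_substrate_map(kin,
                       tibble::tibble(substrate_id = panel_ids,
                                      chip_type = chip),
                       edges)
}

test_that("kinase statistic is the mean LFC of mapped, measured substrates", {
  ids <- sprintf("PTK_%03d", 1:7)
  st <- mk_stats_means(c(0.4, 0.8, 0, 0, 0, 0, 0), ids = ids)
  map <- map_from_sets(list(KA = ids[1:2], KB = ids[3:7]), ids)
  expect_equal(kinase_statistic(st, map, "KA"), 0.6)
  expect_equal(kinase_statistic(st, map, "KB"), 0)
  # independent mean over a 7-substrate set
  withr::with_seed(2, lfcs <- rnorm(7))
  st2 <- mk_stats_means(lfcs, ids = ids)
  map2 <- map_from_sets(list(KC = ids), ids)
  expect_equal(kinase_statistic(st2, map2, "KC"), mean(lfcs),
               tolerance = 1e-12)
})

test_that("an unmeasured kinase is unscorable", {
  ids <- sprintf("PTK_%03d", 1:4)
  st <- mk_stats_means(c(0, 0, 0, 1), ids = ids)
  map <- map_from_sets(list(KA = ids[1:2]), c(ids, "PTK_099"))
  map$edges <- dplyr::bind_rows(map$edges, tibble::tibble(
    kinase_id = "GHOST", substrate_id = "PTK_099", weight = 0.5))
  map$kinases <- dplyr::bind_rows(map$kinases, tibble::tibble(
    kinase_id = "GHOST", family_group = "TK"))
  expect_error(kinase_statistic(st, map, "GHOST"),
               class = "kinomechip_unscorable")
})

test_that("exhaustive Z matches hand enumeration on the 4-substrate example", {
  ids <- sprintf("PTK_%03d", 1:4)
  st <- mk_stats_means(c(0, 0, 0, 1), ids = ids)
  map <- map_from_sets(list(KA = ids[1:2]), ids)
  z <- exhaustive_z(st, map, "KA", min_substrates = 2)
  # all C(4,2)=6 pair means: three 0, three 0.5 -> mean .25, pop sd .25
  expect_equal(z$null_mean, 0.25)
  expect_equal(z$null_sd, 0.25)
  expect_equal(z$z, -1)
  expect_equal(z$n_subsets, 6)
})

test_that("degenerate nulls raise classified errors", {
  ids <- sprintf("PTK_%03d", 1:6)
  st_const <- mk_stats_means(rep(0.3, 6), ids = ids)
  map <- map_from_sets(list(KA = ids[1:3]), ids)
  expect_error(sampling_z(st_const, map, "KA", n_iter = 100, seed = 1),
               class = "kinomechip_degenerate")
  # m == panel size: null undefined
  map_all <- map_from_sets(list(KB = ids), ids)
  st <- mk_stats_means(c(0, 1, 2, 3, 4, 5), ids = ids)
  expect_error(sampling_z(st, map_all, "KB", seed = 1),
               class = "kinomechip_degenerate")
  expect_error(exhaustive_z(st, map_all, "KB"),
               class = "kinomechip_degenerate")
  # symmetric panel: exhaustive null mean is 0
  st_sym <- mk_stats_means(c(-0.4, 0.4, -0.7, 0.7), ids = ids[1:4])
  map_sym <- map_from_sets(list(KC = ids[1:2]), ids[1:4])
  expect_equal(exhaustive_z(st_sym, map_sym, "KC", min_substrates = 2)$null_mean,
               0, tolerance = 1e-12)
})

test_that("sampling Z converges to the exhaustive Z", {
  ids <- sprintf("PTK_%03d", 1:6)
  withr::with_seed(3, lfcs <- rnorm(6))
  st <- mk_stats_means(lfcs, ids = ids)
  map <- map_from_sets(list(KA = ids[1:2]), ids)
  exact <- exhaustive_z(st, map, "KA", min_substrates = 2)$z
  sampled <- sampling_z(st, map, "KA", n_iter = 20000, seed = 11,
                        min_substrates = 2)$z
  expect_lt(abs(sampled - exact), 3 / sqrt(20000) * 10)
  # observed equal to the null mean gives z ~ 0 (exact for exhaustive)
  st0 <- mk_stats_means(rep(c(-1, 1), 3), ids = ids)
  map0 <- map_from_sets(list(KB = ids[1:2]), ids)
  expect_equal(exhaustive_z(st0, map0, "KB", min_substrates = 2)$z, 0,
               tolerance = 1e-12)
})

test_that("sampling Z respects the enumeration bound guard", {
  ids <- sprintf("PTK_%03d", 1:60)
  withr::with_seed(4, lfcs <- rnorm(60))
  st <- mk_stats_means(lfcs, ids = ids)
  map <- map_from_sets(list(KA = ids[1:12]), ids)
  expect_error(exhaustive_z(st, map, "KA"), class = "kinomechip_size")
})

test_that("UKA ranking recovers a spiked kinase and is antisymmetric", {
  n_panel <- 60
  ids <- sprintf("PTK_%03d", seq_len(n_panel))
  withr::with_seed(9, {
    base <- rnorm(n_panel, sd = 0.1)
    pairs <- lapply(seq_len(n_panel), function(i) {
      setNames(base[i] + rnorm(3, sd = 0.05), c("p1", "p2", "p3"))
    })
  })
  spiked <- 1:8
  pairs[spiked] <- lapply(pairs[spiked], function(v) v + 1.0)
  st <- mk_stats(ids, pairs)
  sets <- list(HOT = ids[spiked], COLD1 = ids[9:16], COLD2 = ids[17:28])
  map <- map_from_sets(sets, ids)
  res <- uka_rank(st, map, n_perm = 300, seed = 2)
  expect_s3_class(res, "uka_result")
  expect_equal(res$kinase_id[res$rank == 1], "HOT")
  expect_gt(res$final_score[res$kinase_id == "HOT"], 0)

  # global sign flip negates scores and preserves the rank order
  st_neg <- st
  st_neg$mean_lfc <- -st_neg$mean_lfc
  st_neg$per_pair_lfc <- lapply(st_neg$per_pair_lfc, function(v) -v)
  res_neg <- uka_rank(st_neg, map, n_perm = 300, seed = 2)
  merged <- dplyr::inner_join(tibble::as_tibble(res),
                              tibble::as_tibble(res_neg),
                              by = "kinase_id", suffix = c("", "_neg"))
  expect_equal(merged$final_score_neg, -merged$final_score, tolerance = 1e-12)
  expect_equal(merged$rank_neg, merged$rank)
})

test_that("all-zero LFCs give all-zero final scores ranked by tie-break", {
  ids <- sprintf("PTK_%03d", 1:12)
  st <- mk_stats(ids, lapply(ids, function(i) c(p1 = 0, p2 = 0)))
  map <- map_from_sets(list(KA = ids[1:4], KB = ids[5:10]), ids)
  res <- suppressWarnings(uka_rank(st, map, n_perm = 150, seed = 1))
  expect_true(all(res$final_score == 0))
  # tie-break: larger m first (FILLER has m = 2 < min_substrates, excluded)
  expect_equal(res$kinase_id, c("KB", "KA"))
  expect_equal(res$rank, c(1L, 2L))
})

test_that("scores are invariant to substrate row order", {
  ids <- sprintf("PTK_%03d", 1:20)
  withr::with_seed(6, {
    pairs <- lapply(ids, function(i) setNames(rnorm(3), c("a", "b", "c")))
  })
  st <- mk_stats(ids, pairs)
  map <- map_from_sets(list(KA = ids[1:5], KB = ids[6:12]), ids)
  r1 <- uka_rank(st, map, n_perm = 200, seed = 5)
  st_shuf <- st[withr::with_seed(7, sample(nrow(st))), ]
  r2 <- uka_rank(st_shuf, map, n_perm = 200, seed = 5)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  z1 <- z_score_kinases(st, map, n_iter = 500, seed = 5)
  z2 <- z_score_kinases(st_shuf, map, n_iter = 500, seed = 5)
  expect_equal(tibble::as_tibble(z1), tibble::as_tibble(z2))
})

test_that("kinome tree export has complete documented columns and round-trips", {
  ids <- sprintf("PTK_%03d", 1:12)
  withr::with_seed(8, pairs <- lapply(ids, function(i) {
    setNames(rnorm(3, mean = 0.3), c("a", "b", "c"))
  }))
  st <- mk_stats(ids, pairs)
  map <- map_from_sets(list(KA = ids[1:4], KB = ids[5:9]), ids)
  res <- uka_rank(st, map, n_perm = 150, seed = 3)
  tree <- kinome_tree_export(res, map)
  expect_named(tree, c("kinase_id", "family_group", "activity", "significance"))
  expect_equal(nrow(tree), nrow(res))
  expect_true(all(tree$significance >= 0))
  # positive statistic -> positive activity column
  expect_equal(sign(tree$activity), sign(res$stat))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tree, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tree), tolerance = 1e-12)
  # missing family -> Other with warning
  res2 <- res
  res2$family_group[1] <- NA
  expect_warning(tree2 <- kinome_tree_export(res2), "Other")
  expect_equal(tree2$family_group[1], "Other")
})
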