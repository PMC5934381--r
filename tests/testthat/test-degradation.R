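test_that("standardization divides by the reference-distance group maximum", {
  tbl <- data.frame(
    transect = "T1", origin = "A",
    distance = c(0.5, 0.5, 2), replicate = c(1, 2, 1),
    spl_db = c(78, 80, 70), modulation_depth = c(90, 95, 60),
    scc = c(1, 1, 0.9))
  std <- standardize_by_origin(tbl)
  expect_equal(std$sspl[2], 1.0)                      # the 80 dB row
  expect_equal(std$sspl[1], 10^(78 / 20) / 10^(80 / 20))
  expect_equal(std$smd[2], 1.0)
  expect_equal(std$smd[3], 60 / 95)
  # a single reference-distance row standardizes to itself
  one <- data.frame(transect = "T1", origin = "B", distance = 0.5,
                    replicate = 1, spl_db = 66, modulation_depth = 70,
                    scc = 1)
  expect_equal(standardize_by_origin(one)$sspl, 1.0)
  expect_equal(standardize_by_origin(one)$smd, 1.0)
})

test_that("standardization matches a brute-force oracle on random tables", {
  withr::with_seed(31, {
    tbl <- data.frame(
      transect = sample(paste0("T", 1:5), 100, TRUE),
      origin = sample(c("A", "B", "C", "D"), 100, TRUE),
      distance = sample(c(0.5, 2, 4, 8, 16), 100, TRUE),
      replicate = sample(1:5, 100, TRUE),
      spl_db = runif(100, 55, 90),
      modulation_depth = runif(100, 20, 100),
      scc = runif(100, 0, 1))
  })
  # make sure every (transect, origin) group has a reference row
  tbl$distance[!duplicated(interaction(tbl$transect, tbl$origin))] <- 0.5
  std <- standardize_by_origin(tbl)
  for (i in seq_len(nrow(tbl))) {
    g <- tbl$transect == tbl$transect[i] & tbl$origin == tbl$origin[i]
    div <- max(10^(tbl$spl_db[g & tbl$distance == 0.5] / 20))
    expect_equal(std$sspl[i], 10^(tbl$spl_db[i] / 20) / div)
  }
  # exactly one SSPL = 1 row per (transect, origin)
  ones <- tapply(std$sspl, interaction(std$transect, std$origin, drop = TRUE),
                 function(v) sum(abs(v - 1) < 1e-12))
  expect_true(all(ones == 1))
})

test_that("groups without reference-distance rows are rejected with a warning", {
  tbl <- data.frame(transect = "T1", origin = "A", distance = c(2, 4),
                    replicate = 1:2, spl_db = c(70, 65),
                    modulation_depth = c(50, 40), scc = c(0.9, 0.8))
  expect_warning(std <- standardize_by_origin(tbl, reference_distance = 0.5),
                 "reference")
  expect_true(all(is.na(std$sspl)))
})

test_that("replicate averaging takes means and skips flagged values", {
  tbl <- data.frame(
    transect = "T1", origin = "A", distance = 2,
    replicate = 1:5,
    spl_db = c(1, 2, 3, 4, 5),
    modulation_depth = c(2, 4, 6, NA, 8),
    scc = c(0.5, 0.5, NA, NA, NA))
  avg <- average_replicates(tbl)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$spl_db, 3)
  expect_equal(avg$modulation_depth, 5)
  expect_equal(avg$scc, 0.5)
  # an all-missing cell stays missing
  tbl$scc <- NA_real_
  expect_true(is.na(average_replicates(tbl)$scc))
  # a single replicate is returned unchanged
  one <- tbl[1, ]
  expect_equal(average_replicates(one)$spl_db, 1)
})

test_that("a constructed local advantage yields a significant contrast", {
  withr::with_seed(7, {
    tbl <- random_degradation_table(n_transects = 5,
                                    origins = c("L", "F1", "F2", "F3"),
                                    local = "L", effect = 0.2)
  })
  rep <- local_vs_foreign_summary(tbl, "L", n_permutations = 2000, seed = 3)
  overall <- rep[rep$metric == "sspl" & rep$distance == "overall", ]
  expect_gt(overall$contrast, 0.1)
  expect_lte(overall$p_value, 0.05)
})

test_that("identically distributed origins give a near-zero contrast", {
  withr::with_seed(8, tbl <- random_degradation_table())
  rep <- local_vs_foreign_summary(tbl, "A", n_permutations = 500, seed = 4)
  overall <- rep[rep$metric == "sspl" & rep$distance == "overall", ]
  expect_lt(abs(overall$contrast), 0.2)
  expect_gt(overall$p_value, 0.01)
})

test_that("the permutation summary is seeded and validates its inputs", {
  withr::with_seed(9, tbl <- random_degradation_table())
  r1 <- local_vs_foreign_summary(tbl, "A", n_permutations = 200, seed = 11)
  r2 <- local_vs_foreign_summary(tbl, "A", n_permutations = 200, seed = 11)
  expect_identical(r1, r2)
  expect_error(local_vs_foreign_summary(tbl, "nope", 10, 1), "not present")
  only <- tbl[tbl$origin == "A", ]
  expect_error(local_vs_foreign_summary(only, "A", 10, 1), "foreign")
})
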