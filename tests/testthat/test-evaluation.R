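test_that("entity-wise deviation follows |predicted - gold| / gold", {
  expect_identical(entity_deviation(100, 100), 0)
  expect_identical(entity_deviation(110, 100), 0.1)
  expect_identical(entity_deviation(90, 120), 0.25)
  expect_identical(entity_deviation(0, 50), 1)
  expect_warning(d <- entity_deviation(5, 0), "gold count 0")
  expect_true(is.na(d))
})

test_that("MAPE is the unweighted mean of included deviations, as a percentage", {
  pred <- tibble::tibble(entity_group = c("a", "b"), count = c(110, 130))
  gold <- tibble::tibble(entity_group = c("a", "b"), count = c(100, 100))
  rep <- mape_report(pred, gold)
  expect_equal(rep$mape, 20)
  expect_identical(rep$n_entities, 2L)
  expect_length(rep$excluded, 0)
  # identical tables -> 0
  rep0 <- mape_report(gold, gold)
  expect_identical(rep0$mape, 0)
  # zero-gold entities are excluded with a warning, not infinite
  gold2 <- tibble::tibble(entity_group = c("a", "b", "c"), count = c(100, 100, 0))
  expect_warning(rep2 <- mape_report(pred, gold2), "excluded from MAPE")
  expect_identical(rep2$excluded, "c")
  expect_equal(rep2$mape, 20)
  # entity only in prediction counts as gold 0 -> excluded
  pred3 <- tibble::tibble(entity_group = c("a", "b", "extra"),
                          count = c(110, 130, 7))
  expect_warning(rep3 <- mape_report(pred3, gold), "extra")
  expect_equal(rep3$mape, 20)
  # entity missing from prediction counts as predicted 0 -> deviation 1
  pred4 <- tibble::tibble(entity_group = "a", count = 100)
  rep4 <- mape_report(pred4, gold)
  expect_equal(rep4$mape, 50)
})

test_that("MAPE equals an independent brute-force oracle to 1e-12 on random tables", {
  set.seed(404)
  entities <- paste0("e", 1:24)
  for (i in 1:200) {
    gold_counts <- sample(1:5000, 24, replace = TRUE)
    pred_counts <- pmax(0, gold_counts + sample(-300:300, 24, replace = TRUE))
    pred <- tibble::tibble(entity_group = entities, count = pred_counts)
    gold <- tibble::tibble(entity_group = entities, count = gold_counts)
    got <- mape_report(pred, gold)$mape
    # brute force, computed element by element without the package's join
    devs <- numeric(0)
    for (j in seq_len(24)) {
      devs <- c(devs, abs(pred_counts[j] - gold_counts[j]) / gold_counts[j])
    }
    expect_equal(got, 100 * sum(devs) / 24, tolerance = 1e-12)
  }
})

test_that("deviations are scale invariant", {
  set.seed(2)
  gold <- tibble::tibble(entity_group = paste0("e", 1:10),
                         count = sample(10:999, 10))
  pred <- dplyr::mutate(gold, count = count + sample(-5:5, 10, replace = TRUE))
  m1 <- mape_report(pred, gold)
  m7 <- mape_report(dplyr::mutate(pred, count = count * 7),
                    dplyr::mutate(gold, count = count * 7))
  expect_equal(m1$table$deviation, m7$table$deviation, tolerance = 1e-12)
  expect_equal(m1$mape, m7$mape, tolerance = 1e-12)
})

test_that("perturbed gold standards move MAPE up from exactly zero", {
  map <- test_map()
  coll <- generate_site(small_profile(seed = 33), map)
  pred <- perturb_gold(coll, map, add_late = 0)$gold
  m0 <- mape_report(pred, perturb_gold(coll, map, add_late = 0)$gold)
  expect_identical(m0$mape, 0)
  prev <- 0
  for (k in c(5, 20, 60)) {
    gold_k <- perturb_gold(coll, map, add_late = k, seed = 8)$gold
    mk <- mape_report(pred, gold_k)$mape
    expect_gte(mk, prev)
    prev <- mk
  }
  expect_gt(prev, 0)
})

test_that("registry comparison reproduces shares against each table's own total", {
  registry <- read_count_table()
  expect_identical(sum(registry$count), 63771L)
  fed <- tibble::tibble(
    entity_group = c("melanoma", "colorectum", "other"),
    count = c(1921L, 1187L, 17885L - 1921L - 1187L)
  )
  cmp <- compare_distributions(fed, registry, labels = c("federation", "registry"))
  mel <- cmp[cmp$entity_group == "melanoma", ]
  expect_identical(mel$share_a, 10.7)
  expect_identical(mel$share_b, 5.3)
  reg_breast <- cmp[cmp$entity_group == "breast", ]
  expect_identical(reg_breast$share_b, 17.7)
  expect_identical(cmp$share_b[cmp$entity_group == "colorectum"], 12.7)
  # identical tables -> all differences zero
  same <- compare_distributions(registry, registry)
  expect_true(all(same$share_diff == 0))
})

test_that("tidiers expose the deviation table and summary", {
  pred <- tibble::tibble(entity_group = c("a", "b"), count = c(110, 130))
  gold <- tibble::tibble(entity_group = c("a", "b"), count = c(100, 100))
  rep <- mape_report(pred, gold)
  expect_identical(nrow(tidy(rep)), 2L)
  g <- glance(rep)
  expect_equal(g$mape, 20)
  expect_identical(g$n_excluded, 0L)
})
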