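# build a case table directly (bypassing the pipeline) for aggregation tests
table_from_cells <- function(cells, site_id = "s1", year = 2022L) {
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(entity_group = cells$entity_group[i], gender = cells$gender[i],
               n = cells$count[i])
  }))
  df <- tibble::tibble(
    pseudonym = sprintf("psn%04d", seq_len(sum(rows$n))),
    gender = rep(rows$gender, rows$n),
    icd10_code = "C43",
    diagnosis_year = year,
    entity_group = rep(rows$entity_group, rows$n),
    site_id = site_id
  )
  df
}

random_site_table <- function(site_id, n_max = 80) {
  entities <- c("melanoma", "breast", "lung", "colorectum")
  n <- sample(10:n_max, 1)
  tibble::tibble(
    pseudonym = sprintf("%s-p%04d", site_id, seq_len(n)),
    gender = sample(c("male", "female", "other"), n, replace = TRUE,
                    prob = c(.45, .45, .1)),
    icd10_code = "C43",
    diagnosis_year = 2022L,
    entity_group = sample(entities, n, replace = TRUE),
    site_id = site_id
  )
}

test_that("cells and marginals below min_cell are suppressed; totals never shrink", {
  cells <- tibble::tibble(entity_group = c("melanoma", "melanoma"),
                          gender = c("male", "female"), count = c(7L, 3L))
  tbl <- table_from_cells(cells)
  agg <- aggregate_site(tbl, disclosure_policy(min_cell = 5))
  m <- agg$cells[agg$cells$gender == "male", ]
  f <- agg$cells[agg$cells$gender == "female", ]
  expect_identical(m$count, 7L)
  expect_false(m$suppressed)
  expect_true(f$suppressed)
  expect_true(is.na(f$count))
  expect_identical(agg$entity_marginals$count, 10L)
  expect_identical(agg$total_cases, 10L)
})

test_that("min_cell = 1 never suppresses anything", {
  set.seed(66)
  tbl <- random_site_table("s1")
  agg <- aggregate_site(tbl, disclosure_policy(min_cell = 1))
  expect_false(any(agg$cells$suppressed))
  expect_false(any(agg$entity_marginals$suppressed))
  expect_identical(sum(agg$cells$count), nrow(tbl))
})

test_that("site totals equal row counts for random tables (conservation)", {
  set.seed(10)
  for (i in 1:20) {
    tbl <- random_site_table(paste0("s", i))
    agg <- aggregate_site(tbl, disclosure_policy(min_cell = sample(1:8, 1)))
    expect_identical(agg$total_cases, nrow(tbl))
    # true (pre-suppression) cells sum to the row count; verify via oracle
    oracle <- central_crosstab(list(tbl))
    expect_identical(sum(oracle$count), nrow(tbl))
    unsup <- merge(agg$cells[!agg$cells$suppressed, ], oracle,
                   by = c("entity_group", "gender"))
    expect_true(all(unsup$count.x == unsup$count.y))
  }
})

test_that("mixed site_ids are refused", {
  tbl <- rbind(random_site_table("a"), random_site_table("b"))
  expect_error(aggregate_site(tbl), "one site_id")
})

test_that("combination sums unsuppressed cells, propagates suppression, is commutative", {
  set.seed(20)
  pol <- disclosure_policy(min_cell = 5)
  tbls <- lapply(c("x", "y", "z"), random_site_table)
  aggs <- lapply(tbls, aggregate_site, policy = pol)
  res <- combine_aggregates(aggs)
  expect_identical(res$combined_total, sum(vapply(tbls, nrow, integer(1))))
  # any site-suppressed cell must be combined-suppressed
  for (agg in aggs) {
    sup <- agg$cells[agg$cells$suppressed, ]
    for (i in seq_len(nrow(sup))) {
      cc <- res$cells[res$cells$entity_group == sup$entity_group[i] &
                        res$cells$gender == sup$gender[i], ]
      expect_true(cc$suppressed)
    }
  }
  # order of sites does not matter
  res_rev <- combine_aggregates(rev(aggs))
  expect_equal(res_rev$cells, res$cells)
  expect_equal(res_rev$entity_marginals, res$entity_marginals)
  expect_identical(res_rev$combined_total, res$combined_total)
  # degenerate combine of one site equals that site
  solo <- combine_aggregates(aggs[1])
  expect_identical(solo$combined_total, aggs[[1]]$total_cases)
  expect_equal(
    dplyr::arrange(solo$cells, entity_group, gender),
    dplyr::arrange(
      dplyr::select(aggs[[1]]$cells, entity_group, gender, count, suppressed),
      entity_group, gender
    )
  )
  expect_error(combine_aggregates(list(aggs[[1]], aggs[[1]])), "duplicate")
  expect_error(combine_aggregates(list()), "no site aggregates")
})

test_that("entity shares are percentages of the scope total, rounded half-up to 1 decimal", {
  cells5 <- tibble::tibble(entity_group = "melanoma", gender = c("male", "female"),
                           count = c(260L, 240L))
  rest5 <- tibble::tibble(entity_group = "breast", gender = "female",
                          count = 1545L)
  tbl5 <- table_from_cells(rbind(cells5, rest5), site_id = "site5")
  agg5 <- aggregate_site(tbl5, disclosure_policy(5))
  res <- combine_aggregates(list(agg5))
  shares <- entity_shares(res, "site5")
  expect_identical(shares$share[shares$entity_group == "melanoma"], 24.4)
  single <- combine_aggregates(list(aggregate_site(
    table_from_cells(tibble::tibble(entity_group = "lung", gender = "male",
                                    count = 37L))
  )))
  expect_identical(entity_shares(single)$share, 100)
})

test_that("gender share estimators: arithmetic-mean definition and pooled recount oracle", {
  # two sites with melanoma shares 60/40 and 80/20 -> mean of sites 70/30
  t1 <- table_from_cells(tibble::tibble(
    entity_group = "melanoma", gender = c("male", "female"), count = c(60L, 40L)
  ), site_id = "s1")
  t2 <- table_from_cells(tibble::tibble(
    entity_group = "melanoma", gender = c("male", "female"), count = c(120L, 30L)
  ), site_id = "s2")
  res <- combine_aggregates(list(aggregate_site(t1), aggregate_site(t2)))
  mos <- gender_shares(res, "mean_of_sites")
  expect_identical(mos$share[mos$gender == "male"], 70)
  expect_identical(mos$share[mos$gender == "female"], 30)
  pooled <- gender_shares(res, "pooled")
  expect_identical(pooled$share[pooled$gender == "male"],
                   round(100 * 180 / 250, 1))
  # single site: both estimators coincide
  solo <- combine_aggregates(list(aggregate_site(t1)))
  expect_equal(gender_shares(solo, "pooled")$share,
               gender_shares(solo, "mean_of_sites")$share)
})

test_that("pooled statistics equal a centralized recount oracle on random federations", {
  set.seed(123)
  for (rep in 1:25) {
    n_sites <- sample(2:5, 1)
    tbls <- lapply(paste0("site", seq_len(n_sites)), random_site_table)
    aggs <- lapply(tbls, aggregate_site, policy = disclosure_policy(min_cell = 1))
    res <- combine_aggregates(aggs)
    oracle <- central_crosstab(tbls)
    got <- dplyr::arrange(res$cells, entity_group, gender)
    want <- dplyr::arrange(oracle, entity_group, gender)
    expect_identical(got$entity_group, want$entity_group)
    expect_identical(got$count, as.integer(want$count))
    expect_identical(res$combined_total, sum(want$count))
  }
})

test_that("serialized aggregates round-trip and contain no sub-threshold count", {
  set.seed(321)
  tbl <- random_site_table("json")
  agg <- aggregate_site(tbl, disclosure_policy(min_cell = 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_site_aggregate(agg, path)
  txt <- paste(readLines(path), collapse = "")
  nums <- as.numeric(unlist(regmatches(txt, gregexpr("[0-9]+", txt))))
  counts <- nums[nums > 0 & nums < 6]
  expect_length(counts, 0)
  expect_false(any(grepl("psn|p[0-9]{4}", txt)))
  back <- read_site_aggregate(path)
  expect_equal(back$cells, agg$cells)
  expect_equal(back$entity_marginals, agg$entity_marginals)
  expect_identical(back$total_cases, agg$total_cases)
})
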