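test_that("exact-mode generation reproduces the cell structure bit-exactly", {
  map <- test_map()
  prof <- small_profile()
  coll <- generate_site(prof, map)
  expect_identical(nrow(coll$reports), 12L + 9L + 15L + 20L)
  groups <- assign_entity_group(coll$reports$icd10_code, map)
  got <- table(groups, coll$reports$gender)
  expect_identical(unname(got["melanoma", "M"]), 12L)
  expect_identical(unname(got["melanoma", "W"]), 9L)
  expect_identical(unname(got["breast", "W"]), 15L)
  expect_identical(unname(got["prostate", "M"]), 20L)
  expect_true(all(format(coll$reports$diagnosis_date, "%Y") == "2022"))
  expect_false(anyDuplicated(coll$reports$patient_id) > 0)
})

test_that("identical profile and seed give identical bytes on disk", {
  map <- test_map()
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_obds_collection(generate_site(small_profile(seed = 11), map), p1)
  write_obds_collection(generate_site(small_profile(seed = 11), map), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  p3 <- withr::local_tempfile(fileext = ".xml")
  write_obds_collection(generate_site(small_profile(seed = 12), map), p3)
  expect_false(identical(readBin(p1, "raw", file.size(p1)),
                         readBin(p3, "raw", file.size(p3))))
})

test_that("multinomial cell counts stay within binomial sampling error of expectation", {
  map <- test_map()
  cells <- list(melanoma = list(M = 3, W = 2), breast = list(W = 4),
                prostate = list(M = 1))
  total <- 1000
  w <- c(3, 2, 4, 1) / 10
  n_seeds <- 100
  violations <- 0L
  for (s in seq_len(n_seeds)) {
    prof <- site_profile("sx", 2022, cells, mode = "multinomial",
                         total = total, seed = s)
    coll <- generate_site(prof, map)
    groups <- assign_entity_group(coll$reports$icd10_code, map)
    key <- paste(groups, coll$reports$gender)
    got <- vapply(c("melanoma M", "melanoma W", "breast W", "prostate M"),
                  function(k) sum(key == k), numeric(1))
    mu <- total * w
    sd3 <- 3 * sqrt(total * w * (1 - w))
    violations <- violations + sum(abs(got - mu) > sd3)
  }
  # 3 sigma ~ 99.7% per cell: over 400 cell draws a handful may exceed
  expect_lt(violations / (4 * n_seeds), 0.02)
})

test_that("generation errors on unknown entity labels and all-zero exact counts", {
  map <- test_map()
  expect_error(
    generate_site(site_profile("s", 2022, list(klingon = list(M = 5))), map),
    "not in the map"
  )
  expect_error(site_profile("s", 2022, list(melanoma = list(M = 0))),
               "all-zero")
})

test_that("a federation writes one file per site and conserves total cases", {
  dir <- withr::local_tempdir()
  prof_yaml <- file.path(dir, "fed.yaml")
  writeLines(c(
    "sites:",
    "  - site_id: a", "    year: 2022", "    mode: exact",
    "    cell_counts: {melanoma: {M: 6, W: 7}}",
    "  - site_id: b", "    year: 2021", "    mode: exact",
    "    cell_counts: {breast: {W: 9}}"
  ), prof_yaml)
  fed <- read_federation_profile(prof_yaml, seed = 5)
  out <- generate_federation(fed, file.path(dir, "xml"))
  expect_identical(nrow(out), 2L)
  expect_true(all(file.exists(out$path)))
  expect_identical(sum(out$n_reports), 6L + 7L + 9L)
  parsed <- parse_obds_collection(out$path[out$site_id == "b"])
  expect_identical(nrow(parsed$reports), 9L)
  expect_identical(parsed$site_id, "b")
})

test_that("the packaged federation profile matches its documented structure", {
  fed <- read_federation_profile(seed = 1)
  expect_length(fed$sites, 6)
  totals <- vapply(fed$sites, function(s) sum(s$cells$count), numeric(1))
  expect_identical(sum(totals), 17885)
  s5 <- fed$sites[[which(vapply(fed$sites, `[[`, character(1), "site_id") ==
                           "site-5")]]
  expect_identical(sum(s5$cells$count), 2045)
  mel <- s5$cells[s5$cells$entity_group == "melanoma", ]
  expect_identical(sum(mel$count), 500)
})

test_that("perturb_gold injects only upward and conserves the injected total", {
  map <- test_map()
  coll <- generate_site(small_profile(seed = 21), map)
  base <- perturb_gold(coll, map, add_late = 0)
  groups <- assign_entity_group(coll$reports$icd10_code, map)
  expect_equal(sum(base$gold$count), nrow(coll$reports))
  expect_equal(base$gold$count[order(base$gold$entity_group)],
               as.integer(table(groups)))
  for (k in c(1, 7, 40)) {
    pert <- perturb_gold(coll, map, add_late = k, seed = 3)
    expect_identical(pert$collection, coll)
    expect_equal(sum(pert$gold$count) - sum(base$gold$count), k)
    joined <- merge(base$gold, pert$gold, by = "entity_group", all = TRUE)
    expect_true(all(joined$count.y >= joined$count.x))
  }
})
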