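test_that("a valid collection parses losslessly and XML round-trips are identity", {
  set.seed(42)
  for (i in 1:20) {
    coll <- random_collection(n = sample(1:30, 1), site_id = paste0("site", i))
    path <- withr::local_tempfile(fileext = ".xml")
    write_obds_collection(coll, path)
    parsed <- parse_obds_collection(path, reference_date = as.Date("2023-06-30"))
    expect_equal(parsed$reports, coll$reports)
    expect_identical(parsed$site_id, coll$site_id)
    expect_identical(parsed$obds_version, coll$obds_version)
    expect_identical(nrow(parsed$rejections), 0L)
  }
})

test_that("writing the same collection twice is byte-identical", {
  set.seed(1)
  coll <- random_collection(20)
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_obds_collection(coll, p1)
  write_obds_collection(coll, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("XML special characters in fields survive a round-trip", {
  reports <- random_reports(1)
  reports$patient_id <- "P<&>\"1"
  reports$quasi_identifier <- "Q&I <X>"
  coll <- obds_collection(reports, site_id = "s&1")
  path <- withr::local_tempfile(fileext = ".xml")
  write_obds_collection(coll, path)
  parsed <- parse_obds_collection(path, reference_date = as.Date("2023-06-30"))
  expect_equal(parsed$reports, coll$reports)
  expect_identical(parsed$site_id, "s&1")
})

test_that("invalid reports are rejected with a coded record, valid ones retained", {
  set.seed(3)
  reports <- random_reports(6)
  reports$gender[2] <- "Q"
  reports$icd10_code[3] <- "X9"
  reports$diagnosis_date[4] <- as.Date("2099-01-01")
  reports$report_id[6] <- reports$report_id[5]
  path <- withr::local_tempfile(fileext = ".xml")
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<oBDSCollection obds_version="2.2.2" site_id="s1">',
    sprintf(paste0('<Report id="%s"><PatientID>%s</PatientID>',
                   '<Gender>%s</Gender>',
                   '<Diagnosis icd10="%s" icd10_version="v" date="%s"/></Report>'),
            reports$report_id, reports$patient_id, reports$gender,
            reports$icd10_code, format(reports$diagnosis_date, "%Y-%m-%d")),
    "</oBDSCollection>"
  )
  writeLines(xml, path)
  parsed <- parse_obds_collection(path, reference_date = as.Date("2023-06-30"))
  expect_identical(nrow(parsed$reports), 2L)
  expect_setequal(parsed$rejections$code,
                  c("INVALID_GENDER", "INVALID_ICD10", "FUTURE_DATE",
                    "DUPLICATE_REPORT_ID"))
  expect_identical(
    parsed$rejections$code[parsed$rejections$report_id == reports$report_id[2]],
    "INVALID_GENDER"
  )
})

test_that("malformed XML and unknown roots raise distinct fatal errors", {
  expect_error(parse_obds_collection("<oBDSCollection><bad"), "malformed XML")
  expect_error(parse_obds_collection("<Wrong/>"), "unknown root element")
})

test_that("the version gate passes supported versions and fails others citing the version", {
  coll <- random_collection(3)
  expect_true(check_obds_version(coll)$pass)
  coll223 <- obds_collection(coll$reports, site_id = "s1",
                             obds_version = "2.2.3")
  chk <- check_obds_version(coll223)
  expect_false(chk$pass)
  expect_identical(chk$version, "2.2.3")
  expect_true(check_obds_version(coll223,
                                 supported = c("2.2.2", "2.2.3"))$pass)
})

test_that("decomposition conserves reports as a multiset and copies site/version down", {
  set.seed(9)
  for (i in 1:10) {
    coll <- random_collection(sample(1:25, 1))
    docs <- decompose_collection(coll)
    expect_length(docs, nrow(coll$reports))
    expect_identical(
      vapply(docs, function(d) d$report$report_id, character(1)),
      coll$reports$report_id
    )
    expect_true(all(vapply(docs, `[[`, character(1), "site_id") == coll$site_id))
    expect_true(all(vapply(docs, `[[`, character(1), "obds_version") ==
                      coll$obds_version))
  }
  empty <- obds_collection(random_reports(0), site_id = "sE")
  expect_warning(docs <- decompose_collection(empty), "empty")
  expect_length(docs, 0)
})

test_that("single-report files use the <site>_<report>.xml naming rule and read back", {
  coll <- random_collection(3, site_id = "ulm")
  docs <- decompose_collection(coll)
  dir <- withr::local_tempdir()
  path <- write_obds_report(docs[[2]], dir)
  expect_identical(basename(path), paste0("ulm_", coll$reports$report_id[2], ".xml"))
  back <- read_obds_report(path, reference_date = as.Date("2023-06-30"))
  expect_equal(back$report, docs[[2]]$report)
  expect_identical(back$site_id, "ulm")
  batch <- read_obds_reports(
    vapply(docs, write_obds_report, character(1), dir = dir),
    reference_date = as.Date("2023-06-30")
  )
  expect_identical(nrow(batch), 3L)
  expect_setequal(batch$report_id, coll$reports$report_id)
})
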