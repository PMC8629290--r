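# Ingestion, validation, nondetect substitution, revisit averaging, pairing.

test_that("well-formed rows parse; malformed rows are rejected with diagnostics", {
  path <- write_survey_lines(c(
    "S1,WSA,1,2004-07-01,stream,5,12.5,TN,0.8,0.01",
    "S2,WSA,1,2004-07-02,lake,6,,DOC,5.2,0.1",
    "S3,WSA,2,,stream,unknown,0.4,TP,0.05,0.002"
  ))
  tbl <- read_survey_table(path)
  expect_equal(nrow(tbl), 3L)
  expect_equal(nrow(rejections(tbl)), 0L)
  expect_s3_class(tbl$date, "Date")
  expect_identical(tbl$visit, c(1L, 1L, 2L))
  expect_identical(tbl$ecoregion, c(5L, 6L, NA_integer_))
  expect_true(is.na(tbl$area_km2[2]))

  bad <- write_survey_lines(c(
    "S1,WSA,1,2004-07-01,river,5,12.5,TN,0.8,0.01",   # bad waterbody
    "S2,WSA,1,2004-07-01,stream,5,12.5,TN,-1,0.01",   # negative value
    "S3,WSA,1,2004-07-01,stream,5,12.5,TN,abc,0.01",  # non-numeric
    "S4,WSA,1,2004-07-01,stream,5,12.5,TN,0.8,0.01",
    "S4,WSA,1,2004-07-01,stream,5,12.5,TN,0.9,0.01"   # duplicate key
  ))
  tbl <- read_survey_table(bad)
  expect_equal(nrow(tbl), 1L)
  rej <- rejections(tbl)
  expect_equal(rej$row, c(1L, 2L, 3L, 5L))
  expect_match(rej$reason[1], "waterbody")
  expect_match(rej$reason[2], "non-negative")
  expect_match(rej$reason[3], "not numeric")
  expect_match(rej$reason[4], "duplicate")
})

test_that("a missing mandatory column is a hard error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,survey_id,visit", "A,WSA,1"), path)
  expect_error(read_survey_table(path), "waterbody")
})

test_that("write/read round trip is byte-identical on canonical input", {
  path <- write_survey_lines(c(
    "S1,WSA,1,2004-07-01,stream,5,12.5,TN,0.8,0.01",
    "S2,WSA,1,,lake,,,DOC,5.2,",
    "S3,NRSA08,1,2008-06-30,stream,unknown,1000000,TP,0,0.002"
  ))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey_table(read_survey_table(path), f1)
  write_survey_table(read_survey_table(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("nondetect zeroes become half the detection limit, detects unchanged", {
  s <- make_samples(c("A", "B", "C"), "WSA", c(0, 0.5, 0),
                    detection_limit_mgL = c(0.02, 0.02, NA))
  out <- replace_nondetects(s)
  expect_equal(out$value_mgL[out$site_id == "A"], 0.01)
  expect_equal(out$value_mgL[out$site_id == "B"], 0.5)
  expect_false("C" %in% out$site_id) # zero with no DL: excluded, flagged
  expect_equal(attr(out, "n_replaced"), 1L)
  expect_equal(nrow(rejections(out)), 1L)
})

test_that("nondetect replacement is idempotent and touches only zeroes", {
  set.seed(11)
  s <- make_samples(sprintf("S%03d", 1:50), "WSA",
                    c(rep(0, 10), runif(40, 0.01, 2)))
  once <- replace_nondetects(s)
  twice <- replace_nondetects(once)
  expect_equal(once, twice, ignore_attr = TRUE) # records identical
  expect_equal(attr(twice, "n_replaced"), 0L) # nothing left to replace
  expect_equal(once$value_mgL[11:50], s$value_mgL[11:50])
  expect_true(all(once$value_mgL > 0))
})

test_that("revisit averaging returns per-site-survey means with visit counts", {
  s <- make_samples(c("A", "A", "B"), "WSA", c(0.2, 0.4, 0.7),
                    visit = c(1L, 2L, 1L), area_km2 = c(10, 10, 20))
  m <- average_revisits(s)
  expect_equal(m$mean_value_mgL[m$site_id == "A"], 0.3)
  expect_equal(m$n_visits[m$site_id == "A"], 2L)
  expect_equal(m$mean_value_mgL[m$site_id == "B"], 0.7)
  expect_equal(m$n_visits[m$site_id == "B"], 1L)
})

test_that("conflicting metadata across revisits is a hard error naming the site", {
  s <- make_samples(c("A", "A"), "WSA", c(0.2, 0.4), visit = c(1L, 2L),
                    ecoregion = c(5L, 6L))
  expect_error(average_revisits(s), "A")
})

test_that("pairing keeps the shared-site intersection, sorted and symmetric", {
  m <- make_means(
    c("A", "B", "C", "B", "A"),
    c("S1", "S1", "S1", "S2", "S2"),
    c(1, 2, 3, 20, 10)
  )
  p <- pair_repeat_sites(m, "S1", "S2", "TN", group = 5)
  expect_equal(p$site_id, c("A", "B"))
  expect_equal(p$value_a_mgL, c(1, 2))
  expect_equal(p$value_b_mgL, c(10, 20))

  q <- pair_repeat_sites(m, "S2", "S1", "TN", group = 5)
  expect_equal(q$site_id, p$site_id)
  expect_equal(q$value_a_mgL, p$value_b_mgL)
  expect_equal(q$value_b_mgL, p$value_a_mgL)

  disjoint <- make_means(c("A", "B"), c("S1", "S2"), c(1, 2))
  expect_warning(e <- pair_repeat_sites(disjoint, "S1", "S2", "TN"),
                 "no shared sites")
  expect_equal(nrow(e), 0L)
})

test_that("generator honours a configured repeat-site count", {
  # two campaigns sharing 790 of their sites by construction, the kind of
  # overlap national river surveys exhibit
  cfg <- synthetic_config(n_sites = 1000, ecoregions = 5, surveys = c("A", "B"),
                          repeat_fraction = 0.79, analytes = "TN", seed = 2)
  m <- average_revisits(replace_nondetects(generate_survey_table(cfg)))
  p <- pair_repeat_sites(m, "A", "B", "TN", group = 5)
  expect_equal(nrow(p), 790L)
})
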