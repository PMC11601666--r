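test_that("exports read back with the five columns located and typed", {
  df <- six_row_export()[1:3, ]
  path <- write_fixture_export(df)
  rec <- read_export(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$name, df$Name)
  expect_equal(rec$quantitative, c(12.5, 6400, 3.2))
  expect_equal(rec$hla, df$HLA)

  # comma dialect is sniffed too
  path2 <- tempfile(fileext = ".csv")
  utils::write.table(df, path2, sep = ",", quote = TRUE, row.names = FALSE)
  rec2 <- read_export(path2)
  expect_equal(rec2$quantitative, rec$quantitative)
})

test_that("a missing mandatory column is a schema error naming the headers", {
  df <- six_row_export()
  df[["Quantitative Measurement"]] <- NULL
  path <- write_fixture_export(df)
  expect_error(read_export(path), "Quantitative Measurement")
})

test_that("censored and unparseable quantitative cells become absent with a warning", {
  df <- six_row_export()[1:3, ]
  df[["Quantitative Measurement"]] <- c("<0.1", "not-a-number", "0.1")
  path <- write_fixture_export(df)
  expect_warning(expect_warning(rec <- read_export(path), "censored"),
                 "unparseable")
  expect_true(is.na(rec$quantitative[1]))
  expect_true(is.na(rec$quantitative[2]))
  expect_equal(rec$quantitative[3], 0.1)
})

test_that("the filter cascade keeps exactly the compliant rows, in order", {
  path <- write_fixture_export(six_row_export())
  rec <- read_export(path)
  kept <- apply_filters(rec)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$name, c("GILGFVFTL + OTH(L9)", "KLVALGINAV + PHOS(L2)"))
  rpt <- attr(kept, "filter_report")
  expect_equal(unname(rpt$removed),
               c(1L, 1L, 1L, 1L))  # one row per failure mode
  expect_equal(rpt$n_input, 6L)
  expect_equal(rpt$n_kept, 2L)
})

test_that("filtering empty input yields empty output with zero counts", {
  rec <- read_export(write_fixture_export(six_row_export()))[0, ]
  kept <- apply_filters(rec)
  expect_equal(nrow(kept), 0L)
  expect_equal(sum(attr(kept, "filter_report")$removed), 0L)
})

test_that("filters are idempotent, conservative, and a no-op on compliant data", {
  for (s in 1:3) {
    sim <- generate_affinity_data(generative_spec(n_records = 30L, seed = s))
    once <- apply_filters(sim$records)
    twice <- apply_filters(once)
    expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)
    rpt <- attr(once, "filter_report")
    expect_equal(rpt$n_kept + sum(rpt$removed), rpt$n_input)
    rpt2 <- attr(twice, "filter_report")
    expect_equal(sum(rpt2$removed), 0L)  # all-compliant input passes whole
  }
})

test_that("the regression target is log10 of IC50 in nM", {
  expect_equal(to_target(1), 0)
  expect_equal(to_target(1000), 3)
  expect_equal(to_target(0.1), -1)
  x <- c(0.5, 3, 47, 900)
  expect_equal(to_target(10 * x) - to_target(x), rep(1, 4))
  expect_true(all(diff(to_target(sort(x))) > 0))
  expect_error(to_target(0), "positive")
  expect_error(to_target(-2), "positive")
  expect_error(to_target(Inf), "positive|finite")
})

test_that("affinity datasets pair records with finite targets", {
  rec <- apply_filters(read_export(write_fixture_export(six_row_export())))
  ds <- affinity_dataset(rec)
  expect_length(ds$targets, nrow(ds$records))
  expect_true(all(is.finite(ds$targets)))
  expect_equal(ds$targets, log10(rec$quantitative))
})
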