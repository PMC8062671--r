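test_that("catalog round-trips through CSV and GeoJSON unchanged", {
  cat0 <- toy_catalog()
  for (fmt in c("csv", "geojson")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_catalog(cat0, path, format = fmt)
    back <- read_catalog(path, format = fmt)
    expect_equal(as.data.frame(back$records), as.data.frame(cat0$records),
                 tolerance = 1e-12)
    expect_equal(back$period, cat0$period)
  }
})

test_that("invalid rows are rejected with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = c("a", "b", "c"), x = 0:2, y = 0:2,
                   year = 2001, month = c(5, 13, 7),
                   size_acres = c(20, 30, -5),
                   cause = c("lightning", "vehicle", "arson"),
                   fuel = NA)
  write.csv(df, path, row.names = FALSE)
  expect_warning(cat1 <- read_catalog(path), "rejected")
  expect_equal(n_fires(cat1), 1)
  rej <- attr(cat1, "rejected")
  expect_setequal(rej$row, c(2, 3))
  expect_match(rej$reason[rej$row == 3], "invalid size")
})

test_that("schema violations and empty files raise typed errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,x,y", path)
  expect_error(read_catalog(path), class = "firescape_schema_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,x,y,year,month,size_acres,cause,fuel", path2)
  expect_error(read_catalog(path2), class = "firescape_empty_error")
  expect_error(read_catalog(tempfile()), class = "firescape_io_error")
})

test_that("cause classification is total, deterministic, and partitions", {
  expect_equal(classify_cause("powerline"), "human_construction")
  expect_equal(classify_cause("lightning"), "natural")
  expect_error(classify_cause("gnomes"), class = "firescape_cause_error")

  vocab <- cause_vocabulary()
  anthro <- vocab$code[vocab$group %in% c("human_transportation",
                                          "human_activity",
                                          "human_construction")]
  expect_length(anthro, 15)
  groups <- classify_cause(anthro)
  # each code maps to exactly one of the three human groups
  expect_true(all(groups %in% c("human_transportation", "human_activity",
                                "human_construction")))
  expect_length(groups, 15)
  # idempotent / deterministic
  expect_identical(classify_cause(vocab$code), classify_cause(vocab$code))
  expect_setequal(unique(classify_cause(vocab$code)), cause_groups())
})

test_that("minimum-size rule keeps fires at or above the fuel threshold", {
  cat0 <- fire_catalog(data.frame(
    id = c("a", "b"), x = 0, y = 0, year = 2001, month = 6,
    size = c(5, 15), cause = "lightning", fuel = "timber"))
  kept <- filter_catalog(cat0, min_size_rule = TRUE)
  expect_equal(kept$records$size, 15)
})

test_that("empty criteria leave a catalog unchanged and order is preserved", {
  cat0 <- toy_catalog()
  same <- filter_catalog(cat0)
  expect_equal(same$records, cat0$records)
  expect_equal(cat0$records$id, toy_catalog()$records$id) # input untouched
})

test_that("period filter matches a brute-force row scan", {
  cfg <- california_like_config(seed = 3, n_fires = 400)
  cfg$period <- c(1920, 2019)
  cat0 <- gen_catalog(cfg)
  got <- filter_catalog(cat0, period = c(2000, 2019))
  oracle <- sum(cat0$records$year >= 2000 & cat0$records$year <= 2019)
  expect_equal(n_fires(got), oracle)
  expect_error(filter_catalog(cat0, period = c(2019, 2000)),
               class = "firescape_argument_error")
})

test_that("size split uses >= at the boundary and partitions exactly", {
  cat0 <- fire_catalog(data.frame(
    id = c("a", "b", "c"), x = 0, y = 0, year = 2001, month = 6,
    size = c(499, 500, 501), cause = "lightning"))
  sp <- split_by_size(cat0, 500)
  expect_setequal(sp$large$records$size, c(500, 501))
  expect_equal(sp$small$records$size, 499)

  cfg <- california_like_config(seed = 9, n_fires = 500)
  big <- gen_catalog(cfg)
  sp2 <- split_by_size(big, 500)
  expect_equal(n_fires(sp2$large) + n_fires(sp2$small), n_fires(big))
  expect_equal(n_fires(sp2$large), sum(big$records$size >= 500))
})

test_that("cause summary arithmetic is exact", {
  cat0 <- fire_catalog(data.frame(
    id = as.character(1:16), x = 0, y = 0, year = 2001, month = 6, size = 20,
    cause = c(rep("lightning", 4), rep("vehicle", 12))))
  sm <- summarize_causes(cat0)
  expect_equal(sm$percentage[sm$group == "natural"], 25.00)
  expect_equal(sum(sm$count), 16)

  cfg <- california_like_config(seed = 5, n_fires = 1000)
  sm2 <- summarize_causes(gen_catalog(cfg))
  expect_equal(sum(sm2$count), 1000)
  expect_lt(abs(sum(sm2$percentage) - 100), 0.02)

  empty <- fire_catalog(data.frame(id = character(0), x = numeric(0),
                                   y = numeric(0), year = numeric(0),
                                   month = numeric(0), size = numeric(0),
                                   cause = character(0)))
  expect_error(summarize_causes(empty), class = "firescape_empty_error")
})

test_that("acre conversion uses the international acre", {
  expect_equal(round(acres_to_km2(1000), 2), 4.05)
  expect_equal(acres_to_km2(0), 0)
  expect_equal(round(acres_to_km2(13488190), 2), 54584.77)
  expect_equal(acres_to_km2(-10), -acres_to_km2(10))
})
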