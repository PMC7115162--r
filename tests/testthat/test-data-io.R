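test_that("the packaged table loads with the documented values", {
  expect_s3_class(fix_obs, "obs_table")
  expect_equal(nrow(fix_obs), 66)
  expect_identical(attr(fix_obs, "n_calibration"), 23L)

  r1 <- fix_obs[1, ]
  expect_equal(r1$dry_biomass, 0.00799)
  expect_equal(r1$hh_backscatter, 0.620443)
  expect_equal(r1$incidence_angle, 27.1885)

  r23 <- fix_obs[23, ]
  expect_equal(r23$soil_moisture, 0.379)
  expect_equal(r23$wet_biomass, 6.1246)
})

test_that("schema and invariant violations are reported by name", {
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines(character(0), tmp)
  expect_error(read_observations(tmp), "column|CSV|rows")

  df <- as.data.frame(fix_obs)
  readr::write_csv(df[setdiff(names(df), "ndvi")], tmp)
  expect_error(read_observations(tmp), "ndvi")

  df2 <- df
  df2$extra <- 1
  readr::write_csv(df2, tmp)
  expect_error(read_observations(tmp), "extra")

  df3 <- df
  df3$wet_biomass[5] <- df3$dry_biomass[5] / 2 # wet below dry
  readr::write_csv(df3, tmp)
  expect_error(read_observations(tmp), "wet_biomass.*point_no 5")

  df4 <- df
  df4$hh_backscatter[10] <- -0.1
  readr::write_csv(df4, tmp)
  expect_error(read_observations(tmp), "hh_backscatter.*point_no 10")

  expect_error(as_obs_table(df, n_calibration = 0), "n_calibration")
  expect_error(as_obs_table(df, n_calibration = 67), "n_calibration")
  expect_error(read_observations(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("the calibration/validation split is an order-preserving partition", {
  expect_equal(nrow(fix_parts$calibration), 23)
  expect_equal(nrow(fix_parts$validation), 43)
  expect_tibble_identical(dplyr::bind_rows(fix_parts), fix_obs)
  expect_equal(anyDuplicated(c(fix_parts$calibration$point_no,
                               fix_parts$validation$point_no)), 0L)

  expect_equal(fix_parts$validation$point_no[1], 24)
  expect_equal(fix_parts$validation$dry_biomass[1], 0.01205)

  two <- as_obs_table(as.data.frame(fix_obs)[1:2, ], n_calibration = 1)
  p2 <- split_observations(two)
  expect_equal(nrow(p2$calibration), 1)
  expect_equal(nrow(p2$validation), 1)
})

test_that("summaries reproduce the calibration ranges the study reports", {
  s <- summarize_observations(fix_parts$calibration)
  g <- function(f, what) s[[what]][s$field == f]

  expect_equal(round(g("soil_moisture", "min"), 3), 0.039)
  expect_equal(g("soil_moisture", "max"), 0.379)
  expect_equal(g("incidence_angle", "min"), 21.025)
  expect_equal(g("incidence_angle", "max"), 31.9592)
  expect_equal(round(g("wet_biomass", "min"), 2), 0.04)
  expect_equal(round(g("wet_biomass", "max"), 1), 7.1)
  expect_equal(round(g("dry_biomass", "max"), 2), 1.16)
  expect_true(all(s$n == 23))

  one <- summarize_observations(fix_obs[7, ])
  expect_equal(one$min, one$max)

  expect_error(summarize_observations(fix_obs[0, ]), "non-empty")
})

test_that("whole-table ranges contain the calibration ranges", {
  s_all <- summarize_observations(fix_obs)
  s_cal <- summarize_observations(fix_parts$calibration)
  merged <- dplyr::left_join(s_all, s_cal, by = "field",
                             suffix = c("_all", "_cal"))
  expect_true(all(merged$min_all <= merged$min_cal))
  expect_true(all(merged$max_all >= merged$max_cal))
})

test_that("write/read round-trips the table bit-identically", {
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(fix_obs, t1)
  back <- read_observations(t1, n_calibration = 23)
  expect_tibble_identical(back, fix_obs)
  write_observations(back, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("decibel/power conversion is a strict inverse pair", {
  x <- c(0.004, 0.1, 0.62, 1, 37)
  expect_equal(db_to_power(power_to_db(x)), x)
  expect_equal(power_to_db(1), 0)
  expect_error(power_to_db(c(0.5, 0)), "positive")
})
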