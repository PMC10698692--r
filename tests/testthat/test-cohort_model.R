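test_that("bone-status classification partitions the T-score axis", {
  expect_equal(as.character(classify_bone_status(c(-2.5, -1, 0, -1.7, -3.2))),
               c("osteoporosis", "normal", "normal", "osteopenia",
                 "osteoporosis"))
  # totality: every finite t fires exactly one branch
  ts <- seq(-6, 3, by = 0.01)
  st <- classify_bone_status(ts)
  expect_false(anyNA(st))
  expect_identical(sum(st == "normal") + sum(st == "osteopenia") +
                     sum(st == "osteoporosis"), length(ts))
  expect_error(classify_bone_status(c(0, NA)), "finite")
  expect_error(classify_bone_status(Inf), "finite")
})

test_that("cohort composition reports counts and one-decimal percents", {
  comp <- classify_cohort(c(rep(0.3, 24), rep(-1.8, 23), rep(-2.9, 17)))
  expect_equal(comp$n, c(24, 23, 17))
  expect_equal(comp$percent, c(37.5, 35.9, 26.6))
  expect_lt(abs(sum(comp$percent) - 100), 0.1)

  all_normal <- classify_cohort(rep(0, 10))
  expect_equal(all_normal$percent, c(100, 0, 0))
  expect_equal(classify_cohort(c(0, -2, -3))$percent, rep(33.3, 3))
  expect_error(classify_cohort(numeric(0)), "empty")
})

test_that("percent sums stay near 100 for random cohorts", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:200, 1)
    comp <- classify_cohort(stats::rnorm(n, -1.5, 1.2))
    expect_lte(abs(sum(comp$percent) - 100), 0.1 + 1e-9)
  }
})

test_that("cohort CSV round trip is lossless", {
  cohort <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))

  # property: randomized generated cohorts survive the round trip
  for (seed in 1:5) {
    co <- generate_cohort(generator_config(n_dtc = 12, n_control = 5),
                          seed = seed)
    p2 <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, p2)
    expect_equal(as.data.frame(read_cohort(p2)), as.data.frame(co))
  }
})

test_that("schema violations are reported precisely", {
  cohort <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort[, setdiff(names(cohort), "tsh")], path)
  expect_error(read_cohort(path), "tsh")

  # unparsable cell names the column and row
  bad <- cohort
  bad$age <- as.character(bad$age)
  bad$age[2] <- "forty"
  utils::write.csv(as.data.frame(bad), path, row.names = FALSE)
  expect_error(read_cohort(path), "row 2")
})

test_that("cohort validation derives BMI and defaults missing flags", {
  cohort <- tiny_cohort()
  cohort$bmi <- NULL
  v <- validate_cohort(cohort)
  expect_equal(v$bmi, cohort$weight_kg / (cohort$height_cm / 100)^2)

  # inconsistent explicit bmi wins, with a warning
  cohort2 <- tiny_cohort()
  cohort2$bmi[1] <- cohort2$bmi[1] + 1
  expect_warning(v2 <- validate_cohort(cohort2), "inconsistent")
  expect_equal(v2$bmi[1], cohort2$bmi[1])

  cohort3 <- tiny_cohort()
  cohort3$current_smoking <- NULL
  expect_warning(v3 <- validate_cohort(cohort3), "current_smoking")
  expect_false(any(v3$current_smoking))

  cohort4 <- tiny_cohort()
  cohort4$tsh[1] <- 0
  expect_error(validate_cohort(cohort4), "tsh")
})

test_that("continuous summaries use sample SD and type-7 quartiles", {
  df <- data.frame(v = c(1, 2, 3, 4))
  s <- summarize_variable(df, "v", "continuous")
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  # brute-force type-7: h = (n-1)p + 1, linear interpolation
  type7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(s$q1, type7(df$v, 0.25))
  expect_equal(s$median, type7(df$v, 0.5))
  expect_equal(s$q3, type7(df$v, 0.75))
  expect_equal(c(s$q1, s$median, s$q3), c(1.75, 2.5, 3.25))

  const <- summarize_variable(data.frame(v = rep(5, 7)), "v", "continuous")
  expect_equal(const$mean, 5)
  expect_equal(const$sd, 0)

  cat_s <- summarize_variable(data.frame(v = c("a", "a", "b")), "v",
                              "categorical")
  expect_equal(cat_s$percent, c(66.7, 33.3))
  expect_error(summarize_variable(data.frame(v = c(NA, NA)), "v"),
               "non-missing")
})
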