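test_that("time origin is each child's first examination", {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(tiny_panel_df(), csv, row.names = FALSE)
  ds <- load_panel(csv)
  expect_s3_class(ds, "weight_panel")
  expect_equal(ds$t, c(0, 1.0, 2.0))
  expect_equal(attr(ds, "n_children"), 1L)
  # initial BMI is the BMI at cohort entry, repeated per record
  expect_equal(unique(ds$initial_bmi), compute_bmi(23.8, 122.4))
})

test_that("ages can be derived from ISO dates via a schema mapping", {
  csv <- tempfile(fileext = ".csv")
  df <- data.frame(kid = "a1", gender = "boy", zone = "urban",
                   dob = "2005-10-01",
                   visit = c("2012-07-15", "2013-07-15", "2014-07-15"),
                   ht = c(120, 126, 131), wt = c(23, 25.5, 28))
  utils::write.csv(df, csv, row.names = FALSE)
  ds <- load_panel(csv, schema = list(child_id = "kid", sex = "gender",
                                      area = "zone", exam_date = "visit",
                                      birth_date = "dob", height = "ht",
                                      weight = "wt"))
  expect_equal(ds$exam_age[1], as.numeric(as.Date("2012-07-15") -
                                            as.Date("2005-10-01")) / 365.25)
  expect_equal(diff(ds$t), c(1, 1), tolerance = 0.01)
  expect_error(load_panel(csv, schema = list(child_id = "nope")),
               "missing column")
})

test_that("duplicate examination ages are an error naming the child", {
  df <- tiny_panel_df(ages = c(6.8, 6.8, 8.8), id = "dup01")
  expect_error(weight_panel(df), "dup01")
})

test_that("complete-case filtering drops children with missing waves", {
  df <- rbind(tiny_panel_df(id = "full"),
              tiny_panel_df(ages = c(6.9, 7.9), heights = c(120, 125),
                            weights = c(22, 24), id = "short"))
  cc <- weight_panel(df, complete_case = TRUE)
  expect_equal(attr(cc, "n_children"), 1L)
  expect_identical(attr(cc, "dropped")$incomplete_children, "short")
  keep <- weight_panel(df, complete_case = FALSE)
  expect_equal(attr(keep, "n_children"), 2L)
  # invalid rows are dropped with a report
  bad <- tiny_panel_df()
  bad$height[2] <- -1
  wp <- weight_panel(bad, complete_case = FALSE)
  expect_equal(nrow(wp), 2L)
  expect_equal(nrow(attr(wp, "dropped")$invalid_rows), 1L)
})

test_that("increments are annualized forward differences, absent on last records", {
  ds <- weight_panel(tiny_panel_df())
  ds <- compute_increments(ds)
  expect_equal(ds$ahi[1], 5.7, tolerance = 1e-9)
  expect_equal(ds$awi[1], 2.6, tolerance = 1e-9)
  expect_true(is.na(ds$ahi[3]) && is.na(ds$awi[3]))
  # annualization: a 2-year gap with 11.4 cm growth is still 5.7 cm/y
  ds2 <- weight_panel(tiny_panel_df(ages = c(6.8, 8.8, 9.8),
                                    heights = c(122.4, 133.8, 139.0),
                                    weights = c(23.8, 29.0, 31.5)))
  ds2 <- compute_increments(ds2)
  expect_equal(ds2$ahi[1], 11.4 / 2, tolerance = 1e-9)
  # increments are invariant to shifting the whole series in time
  shifted <- tiny_panel_df()
  shifted$exam_age <- shifted$exam_age + 1.3
  expect_equal(compute_increments(weight_panel(shifted))$ahi,
               ds$ahi, tolerance = 1e-9)
})

test_that("transition counts enumerate consecutive-wave state pairs", {
  df <- tiny_panel_df(ages = c(6.8, 7.8, 8.8, 9.8),
                      heights = c(120, 125, 130, 134),
                      weights = c(22, 25, 27, 31))
  ds <- weight_panel(df)
  ds$state <- c(1L, 2L, 2L, 3L)
  m <- count_transitions(ds)
  expect_equal(m["normal", "overweight"], 1L)
  expect_equal(m["overweight", "overweight"], 1L)
  expect_equal(m["overweight", "obese"], 1L)
  expect_equal(sum(m), 3L)
  # all-constant states give a diagonal-only matrix
  ds$state <- rep(2L, 4)
  m2 <- count_transitions(ds)
  expect_equal(sum(m2) - sum(diag(m2)), 0L)
  # matrix total is records minus children
  set.seed(71)
  coh <- generate_cohort(sim_config(n_children = 120))
  m3 <- count_transitions(coh$panel)
  expect_equal(sum(m3), nrow(coh$panel) - attr(coh$panel, "n_children"))
})

test_that("baseline summary compares sexes with rank and chi-squared tests", {
  set.seed(5)
  n <- 2000  # 50/50 sex split by construction
  df <- data.frame(
    child_id = sprintf("c%04d", rep(seq_len(n), each = 2)),
    sex = rep(rep(c("girl", "boy"), length.out = n), each = 2),
    area = "urban",
    exam_age = rep(c(6.8, 7.8), n),
    height = 122 + stats::rnorm(2 * n, 0, 4))
  bmi_target <- 15.9 + 0.7 * (df$sex == "boy") + stats::rnorm(2 * n, 0, 1.2)
  df$weight <- bmi_target * (df$height / 100)^2
  ds <- weight_panel(df)
  bs <- baseline_summary(ds)
  n_row <- bs[bs$variable == "n", ]
  expect_match(n_row$girls, "50.0")
  expect_match(n_row$boys, "50.0")
  p_bmi <- bs$p[grepl("BMI", bs$variable)]
  expect_lt(p_bmi, 0.05)
  # identical groups (boys' BMI values an exact copy of girls'): p = 1
  df0 <- df
  vals <- rep(15.9 + stats::rnorm(n / 2, 0, 1.2), each = 2)  # one per girl
  bmi0 <- rep(NA_real_, 2 * n)
  bmi0[df0$sex == "girl"] <- vals
  bmi0[df0$sex == "boy"] <- vals
  df0$height <- 122  # identical heights so BMI carries the comparison
  df0$weight <- bmi0 * (122 / 100)^2
  bs0 <- baseline_summary(weight_panel(df0))
  expect_gt(bs0$p[grepl("BMI", bs0$variable)], 0.95)
})
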