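# A hand-built curve object for rate tests, bypassing the smoother.
fake_curve <- function(ages, values, sex = "male", measure = "total_cc") {
  structure(list(age = ages, fitted = values, sex = sex, measure = measure,
                 n = length(ages), config = loess_config()),
            class = "cc_curve")
}

test_that("growth-change rate matches its printed formula on closed forms", {
  # no change
  r <- growth_change_rate(fake_curve(1:2, c(100, 100)))
  expect_equal(r$rate, 0)
  # (125 - 100) / 125 * 100 = 20
  r <- growth_change_rate(fake_curve(1:2, c(100, 125)))
  expect_equal(r$rate, 20)
  # geometric growth: constant rate (1 - 1/1.05) * 100
  v <- 100 * 1.05^(0:10)
  r <- growth_change_rate(fake_curve(0:10, v))
  expect_equal(r$rate, rep((1 - 1 / 1.05) * 100, 10), tolerance = 1e-12)
  expect_equal(r$age_months, 1:10)
})

test_that("the rate series is invariant to positive rescaling of the curve", {
  set.seed(4)
  v <- cumsum(abs(rnorm(20))) + 5
  r1 <- growth_change_rate(fake_curve(1:20, v))
  r2 <- growth_change_rate(fake_curve(1:20, 17.3 * v))
  expect_equal(r1$rate, r2$rate, tolerance = 1e-12)
})

test_that("zero fitted values are flagged undefined, not dropped", {
  r <- growth_change_rate(fake_curve(1:4, c(5, 0, 5, 10)))
  expect_equal(r$undefined, c(TRUE, FALSE, FALSE))
  expect_true(is.na(r$rate[1]))
  expect_equal(nrow(r), 3)
})

test_that("local maxima are positive-to-nonpositive rate crossings away from endpoints", {
  # rates +1, +0.5, -0.2, -1 on months 2..5 -> peak at month 3
  v <- c(100)
  for (rt in c(1, 0.5, -0.2, -1)) v <- c(v, v[length(v)] / (1 - rt / 100))
  r <- growth_change_rate(fake_curve(1:5, v))
  expect_equal(r$rate, c(1, 0.5, -0.2, -1), tolerance = 1e-12)
  expect_equal(find_local_maxima(r), 3)

  # strictly increasing curve: no peaks
  r_up <- growth_change_rate(fake_curve(1:10, exp((1:10) / 10)))
  expect_equal(find_local_maxima(r_up), numeric(0))

  # an interior downturn is a peak even when it is the last possible month
  r_end <- growth_change_rate(fake_curve(1:4, c(1, 2, 3, 2.5)))
  expect_equal(find_local_maxima(r_end), 3)
  # a curve that only ever declines has no positive-to-nonpositive crossing
  r_down <- growth_change_rate(fake_curve(1:6, c(10, 9, 8, 7, 6, 5)))
  expect_equal(find_local_maxima(r_down), numeric(0))
})

test_that("the generative peak of a synthetic bump cohort is recovered", {
  co <- generate_cohort(uniform_cohort_design(200), flat_growth_model(),
                        seed = 20)
  sub <- co[co$sex == "male", ]
  fit <- lowess_fit(sub$age_months, sub$total_cc, loess_config(alpha = 0.4),
                    sex = "male", measure = "total_cc")
  peaks <- find_local_maxima(growth_change_rate(fit))
  expect_gt(length(peaks), 0)
  expect_true(any(abs(peaks - 210) <= 12))
})

test_that("fit_all covers all 16 strata and is deterministic", {
  co <- generate_cohort(seed = 14)
  traj <- fit_all(co, loess_config())
  expect_equal(nrow(traj$strata), 16)
  expect_true(all(traj$strata$fitted))
  expect_equal(nrow(dplyr::distinct(traj$curves[, c("sex", "measure")])), 16)
  traj2 <- fit_all(co, loess_config())
  expect_identical(traj$curves, traj2$curves)
  expect_identical(traj$peaks, traj2$peaks)
})

test_that("single-sex cohorts fit 8 strata and warn about the rest", {
  co <- generate_cohort(seed = 14)
  males <- co[co$sex == "male", ]
  ws <- capture_warnings(traj <- fit_all(males, loess_config()))
  expect_length(ws, 8)
  expect_match(ws, "skipped", all = TRUE)
  expect_equal(sum(traj$strata$fitted), 8)
  expect_true(all(traj$strata$sex[!traj$strata$fitted] == "female"))
})
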