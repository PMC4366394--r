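test_that("cohort generation is deterministic given a seed and matches the design", {
  a <- generate_cohort(seed = 7)
  b <- generate_cohort(seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(seed = 8)))

  expect_equal(nrow(a), 114)
  expect_equal(sum(a$sex == "male"), 61)
  expect_equal(sum(a$sex == "female"), 53)

  # cell counts follow the design exactly
  tab <- table(a$sex, assign_age_group(a$age_months))
  expect_equal(as.vector(tab["male", ]), c(19, 18, 17, 7))
  expect_equal(as.vector(tab["female", ]), c(10, 21, 15, 7))
})

test_that("subject streams make subsets reproducible", {
  full <- generate_cohort(seed = 3)
  male_only <- default_cohort_design()[1:4, ]
  males <- generate_cohort(male_only, seed = 3)
  expect_equal(males[, -1], full[full$sex == "male", -1])
})

test_that("noise-free areas follow the closed-form growth mean", {
  model <- flat_growth_model(asymptote = 100, tau = 10, t_peak = NA,
                             decline = 0, cv = 0)
  design <- uniform_cohort_design(10, age_min = 290, age_max = 300)
  co <- generate_cohort(design, model, seed = 1)
  # t >> tau: every region within 1% of the asymptote
  for (r in cc_regions()) {
    expect_true(all(abs(co[[r]] - 100) < 1))
  }
  # exact closed form at the sampled ages
  expect_equal(co$genu, growth_mean(co$age_months, 100, 10), tolerance = 1e-12)
})

test_that("noise-free areas are nondecreasing in age when there is no decline", {
  model <- flat_growth_model(asymptote = 80, tau = 30, t_peak = NA,
                             decline = 0, cv = 0)
  co <- generate_cohort(uniform_cohort_design(60), model, seed = 5)
  co <- co[order(co$age_months), ]
  for (s in c("male", "female")) {
    sub <- co[co$sex == s, ]
    expect_true(all(diff(sub$total_cc) >= -1e-12))
  }
})

test_that("total callosal area is exactly the sum of the seven subregions", {
  co <- generate_cohort(seed = 11)
  expect_equal(co$total_cc, rowSums(co[, cc_regions()]), tolerance = 0)
})

test_that("lognormal noise has approximately unit mean and the requested cv", {
  model <- flat_growth_model(asymptote = 100, tau = 5, t_peak = NA,
                             decline = 0, cv = 0.2)
  co <- generate_cohort(uniform_cohort_design(400, 250, 300), model,
                        seed = 9)
  vals <- co$genu / growth_mean(co$age_months, 100, 5)
  expect_equal(mean(vals), 1, tolerance = 0.02)
  expect_lt(abs(sd(vals) - 0.2), 0.02)
})

test_that("invalid designs and models are rejected as configuration errors", {
  bad <- default_cohort_design()
  bad$n[1] <- -1L
  expect_error(generate_cohort(bad), class = "ccmorph_config_error")

  expect_error(flat_growth_model(asymptote = -5),
               class = "ccmorph_config_error")
  expect_error(flat_growth_model(t_peak = 10), class = "ccmorph_config_error")
  # a decline that drives the mean negative before 300 months is refused
  expect_error(flat_growth_model(asymptote = 10, decline = 0.01),
               class = "ccmorph_config_error")
})
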