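test_that("the published cell sizes give the published error dfs", {
  co <- generate_cohort(seed = 2)
  res <- mixed_anova(co)
  between <- res[res$effect %in% c("sex", "age_group", "sex:age_group"), ]
  expect_true(all(between$df2 == 106))
  within <- res[grepl("region", res$effect), ]
  expect_true(all(within$df2 == 636))
  expect_equal(res$df1[res$effect == "age_group"], 3)
  expect_equal(res$df1[res$effect == "region"], 6)
  expect_equal(res$df1[res$effect == "age_group:region"], 18)
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("error dfs follow n - 8 and 6(n - 8) for any full 2x4 cohort", {
  design <- default_cohort_design()
  design$n <- c(5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L)
  co <- generate_cohort(design, seed = 30)
  n <- nrow(co)
  res <- mixed_anova(co)
  expect_equal(unique(res$df2[res$effect %in%
                                c("sex", "age_group", "sex:age_group")]),
               n - 8)
  expect_equal(unique(res$df2[grepl("region", res$effect)]), 6 * (n - 8))
})

test_that("every F statistic is invariant to affine transforms of the data", {
  co <- generate_cohort(seed = 6)
  shifted <- co
  for (r in cc_regions()) shifted[[r]] <- 2 * shifted[[r]] + 5
  shifted$total_cc <- rowSums(shifted[, cc_regions()])
  a <- mixed_anova(co)
  b <- mixed_anova(shifted)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-8)
  expect_equal(a$df1, b$df1)
  expect_equal(a$df2, b$df2)
})

test_that("a balanced toy design matches the explicit sums-of-squares oracle", {
  co <- balanced_toy_cohort(n_per_cell = 3)
  res <- mixed_anova(co)
  oracle <- brute_mixed_f(co)
  got <- c(
    sex = res$statistic[res$effect == "sex"],
    age_group = res$statistic[res$effect == "age_group"],
    sex_age = res$statistic[res$effect == "sex:age_group"],
    region = res$statistic[res$effect == "region"],
    region_sex = res$statistic[res$effect == "sex:region"],
    region_age = res$statistic[res$effect == "age_group:region"],
    region_sex_age = res$statistic[res$effect == "sex:age_group:region"]
  )
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("type II and type III agree on balanced data and differ when unbalanced", {
  bal <- balanced_toy_cohort(n_per_cell = 4)
  expect_equal(mixed_anova(bal, ss_type = 2)$statistic,
               mixed_anova(bal, ss_type = 3)$statistic, tolerance = 1e-8)
  unbal <- generate_cohort(seed = 2)
  t2 <- mixed_anova(unbal, ss_type = 2)
  t3 <- mixed_anova(unbal, ss_type = 3)
  expect_false(isTRUE(all.equal(t2$statistic, t3$statistic)))
})

test_that("empty and single-subject cells raise analysis errors naming the cell", {
  co <- generate_cohort(seed = 2)
  no_female_adults <- co[!(co$sex == "female" & co$age_months >= 216), ]
  expect_error(mixed_anova(no_female_adults),
               regexp = "female x adult", class = "ccmorph_analysis_error")
  one_left <- co[!(co$sex == "female" & co$age_months >= 216) |
                   co$subject_id == co$subject_id[co$sex == "female" &
                                                    co$age_months >= 216][1], ]
  expect_error(mixed_anova(one_left), class = "ccmorph_analysis_error")
})

test_that("the between-subjects ANOVA on totals mirrors the mixed between effects", {
  co <- generate_cohort(seed = 8)
  tot <- between_anova(co, "total_cc")
  expect_equal(tot$df2, rep(106L, 3))
  expect_equal(tot$effect, c("sex", "age_group", "sex:age_group"))
  brain <- between_anova(co, "whole_brain_mL")
  expect_gt(brain$statistic[brain$effect == "age_group"], 1)
})
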