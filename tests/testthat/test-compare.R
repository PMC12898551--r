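mk_props <- function(recon, contra) {
  rbind(data.frame(case = "1", side = "reconstructed", small = recon[1],
                   medium = recon[2], large = recon[3], n = 100),
        data.frame(case = "1", side = "contralateral", small = contra[1],
                   medium = contra[2], large = contra[3], n = 100))
}

test_that("side differences are signed reconstructed minus contralateral", {
  p <- mk_props(c(0.5, 0.3, 0.2), c(0.3, 0.4, 0.3))
  expect_equal(side_difference(p, "small"), 0.2)
  expect_equal(side_difference(p, "medium"), -0.1)
  expect_equal(side_difference(mk_props(c(0, 0, 1), c(1, 0, 0)), "small"), -1)
  expect_equal(side_difference(mk_props(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3)),
                               "large"), 0)
  expect_error(side_difference(p[1, ], "small"), "one row per side")
  # differences across the three classes cancel (each side sums to 1)
  d <- vapply(c("small", "medium", "large"),
              function(cl) side_difference(p, cl), numeric(1))
  expect_equal(sum(d), 0)
})

test_that("trend fitting matches closed forms and the OLS oracle", {
  tr <- fit_trend(data.frame(interval_months = c(0, 10), difference = c(0, 10)))
  expect_equal(tr$slope, 1)
  expect_equal(tr$intercept, 0)

  flat <- fit_trend(data.frame(interval_months = c(3, 12, 30),
                               difference = c(0.2, 0.2, 0.2)))
  expect_equal(flat$slope, 0)

  expect_error(fit_trend(data.frame(interval_months = c(5, 5),
                                    difference = c(0, 1))), "undefined slope")
  expect_error(fit_trend(data.frame(interval_months = 5, difference = 0)),
               "at least 2")

  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- sample(0:36, n, replace = FALSE)
    y <- runif(n, -1, 1)
    tr <- fit_trend(data.frame(interval_months = x, difference = y))
    o <- oracle_ols(x, y)
    expect_lt(abs(tr$slope - o["slope"]) / max(abs(o["slope"]), 1e-12), 1e-10)
    expect_lt(abs(tr$intercept - o["intercept"]) /
                max(abs(o["intercept"]), 1e-12), 1e-10)
  }
})

test_that("summaries reproduce the cohort's printed statistics", {
  demo <- cohort_demographics()
  iv <- summarize_values(demo$interval_months, "median_range", "interval")
  expect_equal(iv$center, 15)
  expect_equal(c(iv$min, iv$max), c(3, 30))
  expect_equal(summarize_values(demo$age_years, "median_range")$center, 54.5)
  expect_equal(range(demo$age_years), c(43, 67))
  expect_equal(summarize_values(demo$bmi, "median_range")$center, 22.3)
  expect_equal(summarize_values(demo$sessions, "median_range")$center, 3.5)

  ms <- summarize_values(c(1, 2, 3), "mean_sd")
  expect_equal(ms$center, 2)
  expect_equal(ms$spread, 1)
  expect_error(summarize_values(numeric(0)), "no values")
})

test_that("the report keeps QC-excluded cases out of profiles only", {
  fake_profile <- function() {
    structure(list(density_pct = seq(30, 2, length.out = 8),
                   scheme = depth_layers(), method = "projection",
                   foreground = rep(1, 8), total = rep(10, 8), n_rois = 4),
              class = "depth_profile")
  }
  set.seed(88)
  cases <- lapply(1:8, function(i) {
    excluded <- i %in% c(2, 5, 8)
    pr <- runif(3); pr <- pr / sum(pr)
    pc <- runif(3); pc <- pc / sum(pc)
    list(case_id = i, interval_months = c(26, 8, 18, 3, 12, 10, 30, 30)[i],
         profiles = if (excluded) NULL else
           list(reconstructed = fake_profile(), contralateral = fake_profile()),
         proportions = rbind(
           data.frame(case = as.character(i), side = "reconstructed",
                      small = pr[1], medium = pr[2], large = pr[3], n = 200),
           data.frame(case = as.character(i), side = "contralateral",
                      small = pc[1], medium = pc[2], large = pc[3], n = 200)),
         qc = NULL)
  })
  rep <- build_report(cases)
  expect_equal(length(unique(rep$profiles$case)), 5)
  expect_equal(length(unique(rep$proportions$case)), 8)
  expect_equal(nrow(rep$trends), 3)
  expect_equal(rep$trends$status, rep("ok", 3))
  expect_equal(rep$summary$value[rep$summary$label == "interval_median_months"], 15)
  # regeneration from identical inputs is identical
  expect_identical(rep, build_report(cases))
})

test_that("a single case yields an undefined trend, not a failure", {
  cases <- list(list(case_id = 1, interval_months = 12, profiles = NULL,
                     proportions = mk_props(c(0.4, 0.4, 0.2), c(0.3, 0.4, 0.3)),
                     qc = NULL))
  rep <- build_report(cases)
  expect_equal(rep$trends$status, rep("undefined", 3))
  expect_true(all(is.na(rep$trends$slope)))
})
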