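# Epidemiological statistics.

test_that("quartile categorization follows the interpolation convention", {
  res <- categorize_stress(1:8)
  expect_equal(unname(res$cutpoints), c(2.75, 6.25))
  expect_equal(as.character(res$category),
               c("low", "low", "medium", "medium", "medium", "medium",
                 "high", "high"))

  expect_warning(all_same <- categorize_stress(rep(2, 10)), "identical")
  expect_true(all(all_same$category == "medium"))

  # scores exactly at a cutpoint stay medium
  res2 <- categorize_stress(c(1, 2, 2, 3))  # Q1 = 1.75, Q3 = 2.25 (type 7)
  expect_equal(as.character(res2$category),
               c("low", "medium", "medium", "high"))

  # partition property and the <= 50% bound on the tails
  set.seed(15)
  for (i in 1:5) {
    x <- round(runif(200, 1, 4), 1)  # heavy ties
    cat_ <- categorize_stress(x)$category
    expect_equal(length(cat_), 200)
    expect_false(anyNA(cat_))
    expect_lte(sum(cat_ == "low"), 100)
    expect_lte(sum(cat_ == "high"), 100)
  }
  expect_error(categorize_stress(1:3), "at least 4")
})

test_that("contingency odds ratios match the closed form and reciprocity", {
  r <- contingency_or(22, 90, 10, 100)
  expect_equal(r$odds_ratio, 22 * 100 / (90 * 10), tolerance = 1e-12)
  expect_equal(r$ci_low,
               exp(log(r$odds_ratio) - 1.96 * sqrt(1/22 + 1/90 + 1/10 + 1/100)),
               tolerance = 1e-12)
  # equal proportions give OR 1
  expect_equal(contingency_or(10, 90, 20, 180)$odds_ratio, 1)

  # reference-swap reciprocity
  set.seed(16)
  for (i in 1:5) {
    cells <- sample(5:200, 4)
    a <- do.call(contingency_or, as.list(cells))
    b <- do.call(contingency_or, as.list(cells[c(3, 4, 1, 2)]))
    expect_equal(a$odds_ratio * b$odds_ratio, 1, tolerance = 1e-12)
  }

  expect_error(contingency_or(0, 5, 5, 5), "continuity")
  cc <- contingency_or(0, 5, 5, 5, continuity = TRUE)
  expect_equal(cc$odds_ratio, (0.5 * 5.5) / (5.5 * 5.5))
})

test_that("logistic regression with no covariates reproduces the 2x2 OR", {
  set.seed(17)
  n <- 400
  tab <- data.frame(exposed = factor(sample(c("no", "yes"), n, TRUE),
                                     c("no", "yes")))
  tab$y <- rbinom(n, 1, ifelse(tab$exposed == "yes", 0.3, 0.15))
  raw <- cohort_or(tab, "y", "exposed", reference = "no")$yes
  adj <- logistic_adjusted_or(tab, "y", "exposed", reference = "no")$yes
  expect_equal(adj$odds_ratio, raw$odds_ratio, tolerance = 1e-6)
  expect_false(adj$adjusted)
})

test_that("adjusted OR recovers a planted effect and holds nominal coverage", {
  cfg <- cohort_sim_config(n_subjects = 50000, or_high = 2.5,
                           confounders = list(smoke = list(type = "binary",
                                                           prob = 0.2,
                                                           log_or = 0.5)),
                           seed = 18)
  sc <- simulate_cohort(cfg)
  adj <- logistic_adjusted_or(sc$cohort, "persistent_wheeze",
                              "stress_category", covariates = "smoke",
                              reference = "low")
  expect_equal(adj$high$odds_ratio, 2.5, tolerance = 0.1 / 2.5)
  expect_true(adj$high$adjusted)

  # null exposure: 95% Wald CI covers 1 in >= 93% of replicates
  covered <- vapply(1:100, function(s) {
    sc0 <- simulate_cohort(cohort_sim_config(n_subjects = 800, or_high = 1,
                                             or_medium = 1,
                                             confounders = list(), seed = s))
    r <- logistic_adjusted_or(sc0$cohort, "persistent_wheeze",
                              "stress_category", reference = "low")$high
    r$ci_low <= 1 && 1 <= r$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})

test_that("geometric-mean ratios are exact and scale invariant", {
  tab <- data.frame(g = factor(rep(c("a", "b"), each = 3), c("a", "b")),
                    y = c(1, 1, 1, 2, 2, 2))
  # perfect fit: lm warns that the summary is unreliable, the point
  # estimate is still the exact geometric-mean ratio
  mr <- suppressWarnings(adjusted_mean_ratio(tab, "y", "g")$b)
  expect_equal(mr$mean_ratio, 2, tolerance = 1e-12)

  set.seed(19)
  tab2 <- data.frame(g = factor(rep(c("a", "b"), 20)),
                     x = rnorm(40), y = exp(rnorm(40)))
  m1 <- adjusted_mean_ratio(tab2, "y", "g", covariates = "x")$b
  tab3 <- tab2; tab3$y <- tab3$y * 7; tab3$x <- 3 * tab3$x - 5
  m2 <- adjusted_mean_ratio(tab3, "y", "g", covariates = "x")$b
  expect_equal(m1$mean_ratio, m2$mean_ratio, tolerance = 1e-10)
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-10)

  tab2$y[3] <- -1
  expect_error(adjusted_mean_ratio(tab2, "y", "g"), "strictly positive.*3")
})

test_that("planted biomarker mean ratio is recovered at n = 5000", {
  # replicate-averaged log MR keeps Monte-Carlo error well inside tolerance
  log_mr <- vapply(20:24, function(s) {
    sc <- simulate_cohort(cohort_sim_config(n_subjects = 5000, seed = s))
    log(adjusted_mean_ratio(sc$cohort, "biomarker", "stress_category",
                            reference = "low")$high$mean_ratio)
  }, numeric(1))
  expect_equal(exp(mean(log_mr)), 1.5, tolerance = 0.03)
})

test_that("representativeness chi-square matches the Pearson closed form", {
  sub <- data.frame(k = rep(c("a", "b"), c(10, 30)))
  full <- data.frame(k = rep(c("a", "b"), c(20, 40)))
  got <- representativeness_chisq(sub, full, "k")
  tab <- matrix(c(10, 30, 20, 40), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_equal(got$df, 1)

  same <- representativeness_chisq(data.frame(k = rep(c("a", "b"), c(5, 10))),
                                   data.frame(k = rep(c("a", "b"), c(20, 40))),
                                   "k")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(representativeness_chisq(data.frame(k = "a"),
                                        data.frame(k = "a"), "k"),
               "single category")
})
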