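test_that("concordance reproduces worked three-patient enumerations", {
  # risks (2,3,1), times (5,3,8), all events: every earlier event carries
  # the higher risk
  expect_equal(concordance_index(c(2, 3, 1), c(5, 3, 8), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(3, 2, 1), c(3, 5, 8), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(3, 5, 8), c(1, 1, 1)), 0)
  # one discordant pair out of three
  expect_equal(concordance_index(c(3, 1, 2), c(3, 5, 8), c(1, 1, 1)), 2 / 3)
  # censoring removes the (5, 8) pair from the comparable set
  expect_equal(
    concordance_index(c(3, 1, 2), c(3, 5, 8), c(1, 0, 1)),
    brute_cindex(c(3, 1, 2), c(3, 5, 8), c(1, 0, 1))
  )
})

test_that("a perfect ordering scores exactly 1", {
  withr::with_seed(3, {
    t <- sort(sample(seq(1, 200, by = 0.5), 50))
    expect_identical(concordance_index(-t, t, rep(1, 50)), 1)
  })
  expect_error(concordance_index(c(1, 2), c(5, 5), c(0, 0)), "comparable")
})

test_that("concordance equals brute-force pair enumeration at small n", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(8:20, 1)
      time <- sample(1:12, n, replace = TRUE) # forces ties in time
      event <- rbinom(n, 1, 0.6)
      risk <- sample(1:6, n, replace = TRUE) # forces ties in risk
      if (sum(event) == 0) event[1] <- 1L
      expect_equal(
        concordance_index(risk, time, event),
        brute_cindex(risk, time, event),
        tolerance = 1e-12
      )
    })
  }
})

test_that("uninformative risks score one half and negation flips C", {
  withr::with_seed(19, {
    oc <- generate_outcomes(rnorm(1000), outcome_spec(beta = 0, seed = 2))
    cis <- vapply(1:10, function(r) {
      concordance_index(rnorm(1000), oc$time_months, oc$event)
    }, numeric(1))
    expect_equal(mean(cis), 0.5, tolerance = 0.03)
    risk <- rnorm(1000)
    ci <- concordance_index(risk, oc$time_months, oc$event)
    expect_equal(
      concordance_index(-risk, oc$time_months, oc$event),
      1 - ci,
      tolerance = 1e-10
    )
  })
})

test_that("bootstrap intervals behave at the edges and cover nominally", {
  const_ci <- bootstrap_ci(function(idx) 1.23, n = 30, n_boot = 50, seed = 1)
  expect_equal(unname(const_ci["lo"]), 1.23)
  expect_equal(unname(const_ci["hi"]), 1.23)
  expect_error(bootstrap_ci(function(idx) 1, n = 5), "at least 10")
  withr::with_seed(7, {
    x <- rnorm(40)
    ci <- bootstrap_ci(function(idx) mean(x[idx]), n = 40, n_boot = 500,
      seed = 5)
    expect_lte(ci["lo"], mean(x))
    expect_gte(ci["hi"], mean(x))
    # coverage of the true mean over replicates
    hits <- vapply(1:300, function(r) {
      y <- rnorm(30, mean = 2)
      ci_r <- bootstrap_ci(function(idx) mean(y[idx]), n = 30,
        n_boot = 200, seed = r)
      ci_r["lo"] <= 2 && ci_r["hi"] >= 2
    }, logical(1))
    expect_equal(mean(hits), 0.95, tolerance = 0.04)
  })
})

test_that("median-risk stratification ties go to the low group", {
  g <- stratify_risk(c(1, 2, 3, 4), c(2.5, 2.6))
  expect_equal(g$cutoff, 2.5)
  expect_equal(as.character(g$valid), c("low", "high"))
  expect_equal(sum(g$explor == "low"), 2) # even split by the median
  expect_warning(stratify_risk(c(1, 2, 3, 4), c(9, 9, 9)), "one risk group")
  expect_error(stratify_risk(numeric(0)), "no exploratory")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 2 / 3) # censoring leaves the curve
  expect_equal(km$surv[km$time == 3], 0)
  # no censoring: equals the empirical survival function
  withr::with_seed(2, {
    t <- sample(1:50, 25, replace = TRUE)
    km2 <- kaplan_meier(t, rep(1, 25))
    for (r in seq_len(nrow(km2))) {
      expect_equal(km2$surv[r], mean(t > km2$time[r]))
    }
  })
  km3 <- kaplan_meier(c(4, 7, 9), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
})

test_that("log-rank: symmetry null, hand example, and type-I control", {
  t0 <- c(2, 4, 6)
  p_same <- logrank_test(
    c(t0, t0), c(1, 1, 1, 1, 1, 1),
    factor(rep(c("a", "b"), each = 3))
  )
  expect_equal(p_same, 1)
  expect_error(
    logrank_test(t0, c(1, 1, 1), factor(rep("a", 3))),
    "two non-empty groups"
  )
  # hand computation for two groups of three distinct event times:
  # observed minus expected under the hypergeometric at each event time
  tt <- c(1, 3, 5, 2, 4, 6)
  ev <- rep(1, 6)
  gg <- factor(rep(c("a", "b"), each = 3))
  oe <- 0
  v <- 0
  ord <- order(tt)
  at_risk_a <- 3
  at_risk <- 6
  for (i in ord) {
    d_a <- as.integer(gg[i] == "a")
    oe <- oe + d_a - at_risk_a / at_risk
    v <- v + (at_risk_a / at_risk) * (1 - at_risk_a / at_risk) *
      (at_risk - 1) / max(at_risk - 1, 1)
    at_risk_a <- at_risk_a - d_a
    at_risk <- at_risk - 1
  }
  p_hand <- 1 - stats::pchisq(oe^2 / v, df = 1)
  expect_equal(logrank_test(tt, ev, gg), p_hand, tolerance = 1e-10)

  withr::with_seed(11, {
    pvals <- vapply(1:1000, function(r) {
      oc <- generate_outcomes(rnorm(40), outcome_spec(beta = 0, seed = r))
      g <- factor(sample(rep(c("lo", "hi"), each = 20)))
      logrank_test(oc$time_months, oc$event, g)
    }, numeric(1))
    expect_gte(mean(pvals < 0.05), 0.03)
    expect_lte(mean(pvals < 0.05), 0.07)
    expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  })
})

test_that("subgroups partition the patients and flag empties", {
  rimcore_log_clear()
  withr::with_seed(4, {
    oc <- generate_outcomes(rnorm(60), outcome_spec(seed = 9))
    risk <- rnorm(60)
    vol <- c(runif(30, 2, 18), runif(30, 25, 120))
    sub <- subgroup_analysis(risk, oc$time_months, oc$event, vol)
    expect_setequal(sub$subgroup, c("small", "large"))
    expect_equal(sum(sub$n), 60)
    sub2 <- subgroup_analysis(risk, oc$time_months, oc$event, rep(5, 60))
    expect_equal(sub2$subgroup, "small")
    expect_true(any(grepl("empty", rimcore_log())))
  })
})

test_that("sub-volume comparison: null, strong constant effect, symmetry", {
  same <- compare_subvolumes(rep(0.6, 30), rep(0.6, 30))
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
  shifted <- compare_subvolumes(rep(0.65, 30), rep(0.60, 30), seed = 2)
  expect_equal(shifted$statistic, 0.05)
  expect_lte(shifted$p_value, 0.001)
  withr::with_seed(6, {
    a <- runif(12, 0.55, 0.7)
    b <- runif(12, 0.5, 0.65)
    ab <- compare_subvolumes(a, b, seed = 3)
    ba <- compare_subvolumes(b, a, seed = 3)
    expect_equal(ab$statistic, -ba$statistic)
    expect_equal(ab$p_value, ba$p_value)
  })
  expect_error(compare_subvolumes(0.6, 0.5), "at least 2")
})

test_that("representative selection picks the median-of-medians combo", {
  grid <- tidyr::expand_grid(
    selector = c("mim", "mrmr", "rfvi"),
    learner = c("cox", "rsf")
  )
  grid$c_index <- c(0.60, 0.62, 0.65, 0.67, 0.70, 0.72)
  rep <- select_representative(grid)
  med_sel <- tapply(grid$c_index, grid$selector, stats::median)
  expect_equal(
    rep$selector,
    names(med_sel)[which.min(abs(med_sel - stats::median(med_sel)))]
  )
  expect_true(rep$learner %in% c("cox", "rsf"))
})

test_that("autoplot produces ggplot objects", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 1),
    factor(c("low", "low", "high", "high"), levels = c("low", "high"))
  )
  expect_s3_class(autoplot(km), "ggplot")
})
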