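test_that("preprocessing z-scores with exploratory statistics only", {
  toy <- toy_features(n = 60)
  ex_ids <- toy$features$patient_id[1:40]
  prep <- preprocess_features(toy$features, ex_ids)
  tab <- prep$table
  ex <- tab$patient_id %in% ex_ids
  for (f in prep$features) {
    expect_equal(mean(tab[[f]][ex]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(tab[[f]][ex]), 1, tolerance = 1e-10)
  }
  # validation rows generally do not have mean 0 / sd 1
  means_v <- vapply(prep$features, function(f) mean(tab[[f]][!ex]), numeric(1))
  expect_gt(max(abs(means_v)), 1e-3)
  expect_error(preprocess_features(toy$features, ex_ids[1]), "fewer than 2")
})

test_that("a duplicated feature collapses into one meta-feature", {
  toy <- toy_features(n = 50)
  feats <- toy$features
  feats$f_copy <- feats$f_signal # perfectly correlated pair
  prep <- preprocess_features(feats, feats$patient_id[1:35])
  expect_false("f_copy" %in% prep$features)
  expect_false("f_signal" %in% prep$features)
  meta <- prep$cluster_map$meta[prep$cluster_map$feature == "f_signal"][1]
  expect_true(meta %in% prep$features)
  members <- prep$cluster_map$feature[prep$cluster_map$meta == meta]
  expect_setequal(members, c("f_signal", "f_copy"))
  # meta-feature equals the shared z-scores
  z <- (feats$f_signal - mean(feats$f_signal[1:35])) /
    stats::sd(feats$f_signal[1:35])
  expect_equal(prep$table[[meta]], z, tolerance = 1e-10)
})

test_that("independent features stay singletons", {
  withr::with_seed(41, {
    n <- 500
    tab <- tibble::tibble(patient_id = sprintf("P%04d", 1:n))
    for (j in 1:12) tab[[sprintf("g%02d", j)]] <- rnorm(n)
    prep <- preprocess_features(tab, tab$patient_id)
    expect_length(prep$features, 12)
    expect_true(all(!grepl("^meta_", prep$features)))
  })
})

test_that("zero-variance features are dropped with a log record", {
  rimcore_log_clear()
  toy <- toy_features(n = 40)
  feats <- toy$features
  feats$f_const <- 3
  prep <- preprocess_features(feats, feats$patient_id[1:30])
  expect_false("f_const" %in% prep$features)
  expect_true(any(grepl("zero-variance", rimcore_log())))
})

test_that("every selector ranks a strong signal feature first", {
  toy <- toy_features(n = 300, n_noise = 12, beta = 2)
  ex_ids <- toy$features$patient_id[1:200]
  prep <- preprocess_features(toy$features, ex_ids)
  extab <- prep$table[prep$table$patient_id %in% ex_ids, ]
  for (sel in c("spearman", "mim", "mifs", "mrmr", "rfvi")) {
    rk <- rank_features(extab, toy$outcomes, sel,
      n_bootstrap = 25, seed = 3
    )
    expect_equal(rk$feature[1], "f_signal", info = sel)
  }
  expect_error(
    rank_features(extab, toy$outcomes, "pca", n_bootstrap = 5),
    "arg"
  )
})

test_that("rankings aggregate by mean rank and are seed-deterministic", {
  toy <- toy_features(n = 120)
  prep <- preprocess_features(toy$features, toy$features$patient_id)
  a <- rank_features(prep$table, toy$outcomes, "mim", n_bootstrap = 15, seed = 9)
  b <- rank_features(prep$table, toy$outcomes, "mim", n_bootstrap = 15, seed = 9)
  expect_identical(a, b)
  expect_true(all(diff(a$mean_rank) >= 0))
})

test_that("mutual information of an independent feature is near zero", {
  withr::with_seed(17, {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, 0.4)
    mi <- rimcore:::mi_disc(rimcore:::ef_bin(x), y)
    expect_lt(mi, 0.01) # estimator bias only
    # strongly dependent pair for contrast
    mi2 <- rimcore:::mi_disc(rimcore:::ef_bin(y + rnorm(1000, 0, 0.1)), y)
    expect_gt(mi2, 0.5)
  })
})

test_that("redundant copies are deferred by the MRMR greedy order", {
  withr::with_seed(23, {
    n <- 400
    y <- rbinom(n, 1, 0.5)
    f1 <- y + rnorm(n, 0, 0.5) # informative
    f2 <- f1 # exact copy: redundant
    f3 <- y + rnorm(n, 0, 0.9) # informative, non-redundant
    x <- cbind(f1 = f1, f2 = f2, f3 = f3)
    rk <- rimcore:::greedy_mi_rank(x, y, beta = NA, depth = 3)
    expect_equal(rk[1], 1) # f1 first (highest relevance)
    expect_lt(rk[3], rk[2]) # f3 chosen before the exact copy f2
  })
})

test_that("hyper-parameter search respects its budget contract", {
  toy <- toy_features(n = 80)
  ex_ids <- toy$features$patient_id[1:60]
  prep <- preprocess_features(toy$features, ex_ids)
  extab <- prep$table[prep$table$patient_id %in% ex_ids, ]
  rk <- rank_features(extab, toy$outcomes, "spearman", n_bootstrap = 5, seed = 1)
  one <- tune_hyperparams("spearman", "cox", extab, toy$outcomes, rk,
    budget = 1, n_bootstrap = 5, seed = 2
  )
  expect_equal(nrow(one$trace), 1)
  expect_true(one$k >= 1 && one$k <= 10)
  expect_error(
    tune_hyperparams("spearman", "cox", extab, toy$outcomes, rk, budget = 0),
    "budget"
  )
  # informative feature setting reaches useful out-of-bag concordance
  tuned <- tune_hyperparams("spearman", "cox", extab, toy$outcomes, rk,
    budget = 3, n_bootstrap = 10, seed = 3
  )
  expect_gt(tuned$score, 0.6)
})

test_that("pure-noise tuning stays near chance", {
  withr::with_seed(29, {
    n <- 120
    tab <- tibble::tibble(patient_id = sprintf("P%04d", 1:n))
    for (j in 1:6) tab[[sprintf("n%02d", j)]] <- rnorm(n)
    oc <- generate_outcomes(rnorm(n), outcome_spec(beta = 0, seed = 5))
    prep <- preprocess_features(tab, tab$patient_id)
    rk <- rank_features(prep$table, oc, "spearman", n_bootstrap = 5, seed = 1)
    tuned <- tune_hyperparams("spearman", "cox", prep$table, oc, rk,
      budget = 2, n_bootstrap = 15, seed = 2
    )
    expect_gt(tuned$score, 0.35)
    expect_lt(tuned$score, 0.65)
  })
})

test_that("a single-model ensemble predicts exactly like its one fit", {
  toy <- toy_features(n = 60)
  prep <- preprocess_features(toy$features, toy$features$patient_id)
  ens <- train_ensemble("spearman", "cox", "f_signal", list(),
    prep$table, toy$outcomes,
    n_bootstrap = 1, seed = 11
  )
  expect_equal(ens$n_fitted, 1)
  pred <- ensemble_predict(ens, prep$table)
  direct <- rimcore:::predict_risk(
    ens$fits[[1]], as.matrix(prep$table[, "f_signal"])
  )
  expect_equal(pred$risk, direct)
})

test_that("ensemble prediction is symmetric in model order", {
  toy <- toy_features(n = 60)
  prep <- preprocess_features(toy$features, toy$features$patient_id)
  ens <- train_ensemble("spearman", "cox", c("f_signal", "f_noise01"),
    list(), prep$table, toy$outcomes,
    n_bootstrap = 8, seed = 12
  )
  p1 <- ensemble_predict(ens, prep$table)
  ens$fits <- rev(ens$fits)
  p2 <- ensemble_predict(ens, prep$table)
  expect_equal(p1$risk, p2$risk)
  expect_error(
    ensemble_predict(ens, prep$table[, "patient_id"]),
    "missing"
  )
})

test_that("Cox ensembles recover the sign and shrink bias with n", {
  bias <- vapply(c(100, 300), function(n) {
    toy <- toy_features(n = n, n_noise = 2, beta = 1.5, seed = 8)
    prep <- preprocess_features(toy$features, toy$features$patient_id)
    ens <- train_ensemble("spearman", "cox", "f_signal", list(),
      prep$table, toy$outcomes,
      n_bootstrap = 20, seed = 13
    )
    coefs <- vapply(ens$fits, function(f) f$fit$coef[["f_signal"]], numeric(1))
    expect_gt(mean(coefs), 0) # generator hazard increases with z
    mean(coefs)
  }, numeric(1))
  expect_lt(abs(diff(bias)) / bias[1], 1) # estimates stabilise
})

test_that("all-censored bootstrap resamples are dropped, not fatal", {
  rimcore_log_clear()
  withr::with_seed(31, {
    n <- 25
    tab <- tibble::tibble(
      patient_id = sprintf("P%04d", 1:n), f = rnorm(n)
    )
    oc <- tibble::tibble(
      patient_id = tab$patient_id,
      time_months = runif(n, 1, 20),
      event = c(1L, rep(0L, n - 1)) # a single event
    )
    ens <- train_ensemble("spearman", "cox", "f", list(), tab, oc,
      n_bootstrap = 40, seed = 3
    )
    expect_lt(ens$n_fitted, 40)
    expect_true(any(grepl("all-censored", rimcore_log())))
  })
})

test_that("every learner trains, predicts finitely, and orients risk upward", {
  toy <- toy_features(n = 150, n_noise = 2, beta = 2, seed = 15)
  ex_ids <- toy$features$patient_id[1:100]
  prep <- preprocess_features(toy$features, ex_ids)
  extab <- prep$table[prep$table$patient_id %in% ex_ids, ]
  vatab <- prep$table[!prep$table$patient_id %in% ex_ids, ]
  oc <- toy$outcomes
  for (lrn in c("cox", "bglm_cox", "bt_cox", "bt_weibull", "rsf", "msr_rf")) {
    ens <- train_ensemble("spearman", lrn, c("f_signal", "f_noise01"),
      list(), extab, oc,
      n_bootstrap = 10, seed = 21
    )
    pred <- ensemble_predict(ens, vatab)
    expect_true(all(is.finite(pred$risk)), info = lrn)
    ocv <- oc[match(vatab$patient_id, oc$patient_id), ]
    ci <- concordance_index(pred$risk, ocv$time_months, ocv$event)
    expect_gt(ci, 0.6) # higher risk must mean earlier recurrence
  }
})

test_that("tidy and glance summarise ensembles in broom style", {
  toy <- toy_features(n = 50)
  prep <- preprocess_features(toy$features, toy$features$patient_id)
  ens <- train_ensemble("mim", "cox", c("f_signal", "f_noise02"), list(),
    prep$table, toy$outcomes,
    n_bootstrap = 3, seed = 2
  )
  td <- tidy(ens)
  expect_equal(td$feature, c("f_signal", "f_noise02"))
  expect_equal(td$rank, 1:2)
  gl <- glance(ens)
  expect_equal(gl$n_bootstrap, 3)
  expect_equal(gl$selector, "mim")
})

test_that("no exploratory-derived quantity leaks from validation outcomes", {
  toy <- toy_features(n = 120, beta = 1.5, seed = 44)
  ex_ids <- toy$features$patient_id[1:80]
  va_ids <- setdiff(toy$features$patient_id, ex_ids)
  oc1 <- toy$outcomes
  oc2 <- oc1
  shuffle <- withr::with_seed(1, sample(va_ids))
  oc2[match(va_ids, oc2$patient_id), c("time_months", "event")] <-
    oc1[match(shuffle, oc1$patient_id), c("time_months", "event")]

  fit1 <- train_risk_model(toy$features, oc1, ex_ids,
    selector = "spearman", learner = "cox",
    n_bootstrap_select = 10, n_bootstrap_train = 10,
    tune_budget = 2, seed = 31
  )
  fit2 <- train_risk_model(toy$features, oc2, ex_ids,
    selector = "spearman", learner = "cox",
    n_bootstrap_select = 10, n_bootstrap_train = 10,
    tune_budget = 2, seed = 31
  )
  expect_identical(fit1$prep$stats, fit2$prep$stats)
  expect_identical(fit1$prep$cluster_map, fit2$prep$cluster_map)
  expect_identical(fit1$ranking, fit2$ranking)
  expect_identical(fit1$tuned$k, fit2$tuned$k)
  expect_identical(fit1$ensemble$signature, fit2$ensemble$signature)
  p1 <- predict(fit1)
  p2 <- predict(fit2)
  expect_equal(p1$risk, p2$risk)
  ex_risk1 <- p1$risk[p1$patient_id %in% ex_ids]
  ex_risk2 <- p2$risk[p2$patient_id %in% ex_ids]
  expect_identical(stats::median(ex_risk1), stats::median(ex_risk2))
})

test_that("full runs with the same master seed are bit-identical", {
  toy <- toy_features(n = 80, seed = 52)
  ex_ids <- toy$features$patient_id[1:55]
  f1 <- train_risk_model(toy$features, toy$outcomes, ex_ids,
    selector = "mrmr", learner = "bglm_cox",
    n_bootstrap_select = 8, n_bootstrap_train = 8, tune_budget = 2, seed = 6
  )
  f2 <- train_risk_model(toy$features, toy$outcomes, ex_ids,
    selector = "mrmr", learner = "bglm_cox",
    n_bootstrap_select = 8, n_bootstrap_train = 8, tune_budget = 2, seed = 6
  )
  expect_identical(predict(f1)$risk, predict(f2)$risk)
})
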