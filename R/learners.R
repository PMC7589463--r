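# The six survival learners behind one fit/predict contract. Every learner
# returns risks oriented so that higher = higher hazard of recurrence.

LEARNERS <- c("cox", "bt_cox", "bglm_cox", "rsf", "msr_rf", "bt_weibull")
SELECTORS <- c("spearman", "mim", "mifs", "mrmr", "rfvi")

default_hyperparams <- function(learner) {
  switch(learner,
    cox = list(),
    bt_cox = list(nrounds = 50, max_depth = 2, eta = 0.1),
    bt_weibull = list(nrounds = 50, max_depth = 2, eta = 0.1),
    bglm_cox = list(mstop = 100, nu = 0.1),
    rsf = list(num_trees = 250, min_node_size = 10),
    msr_rf = list(num_trees = 250, min_node_size = 10),
    stop("unknown learner: ", learner, call. = FALSE)
  )
}

# random-search grids for hyper-parameter optimisation
hyperparam_grid <- function(learner) {
  switch(learner,
    cox = list(),
    bt_cox = ,
    bt_weibull = list(
      nrounds = c(25, 50, 100), max_depth = 1:3, eta = c(0.05, 0.1, 0.3)
    ),
    bglm_cox = list(mstop = c(50, 100, 250), nu = c(0.05, 0.1)),
    rsf = ,
    msr_rf = list(
      num_trees = c(100, 250, 500), min_node_size = c(5, 10, 20)
    ),
    stop("unknown learner: ", learner, call. = FALSE)
  )
}

fit_learner <- function(learner, x, time, event, params = list(),
                        seed = 1L) {
  params <- utils::modifyList(default_hyperparams(learner), params)
  x <- as.matrix(x)
  if (sum(event) == 0) stop("all-censored sample", call. = FALSE)
  fit <- switch(learner,
    cox = fit_cox(x, time, event),
    bglm_cox = fit_bglm_cox(x, time, event, params),
    bt_cox = fit_xgb_cox(x, time, event, params, seed),
    bt_weibull = fit_xgb_aft(x, time, event, params, seed),
    rsf = fit_ranger_surv(x, time, event, params, seed, "logrank"),
    msr_rf = fit_ranger_surv(x, time, event, params, seed, "maxstat")
  )
  structure(list(learner = learner, fit = fit, features = colnames(x)),
    class = "rimcore_learner"
  )
}

predict_risk <- function(object, x) {
  x <- as.matrix(x)[, object$features, drop = FALSE]
  switch(object$learner,
    cox = as.numeric(x %*% object$fit$coef),
    bglm_cox = as.numeric(x %*% object$fit$coef),
    bt_cox = as.numeric(
      stats::predict(object$fit, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
    ),
    bt_weibull = -as.numeric(
      stats::predict(object$fit, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
    ),
    rsf = ,
    msr_rf = {
      ch <- stats::predict(
        object$fit,
        data = as.data.frame(x),
        num.threads = 1
      )$chf
      rowSums(ch)
    }
  )
}

fit_cox <- function(x, time, event) {
  df <- as.data.frame(x)
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")
  ))
  fit <- suppressWarnings(survival::coxph(fml, data = df))
  cf <- stats::coef(fit)
  if (all(!is.finite(cf))) stop("coxph did not converge", call. = FALSE)
  if (any(!is.finite(cf))) {
    # aliased (collinear) columns: contribute nothing, as survival does
    rc_log("fit_cox: %d aliased coefficients set to 0", sum(!is.finite(cf)))
    cf[!is.finite(cf)] <- 0
  }
  list(coef = cf)
}

# componentwise linear gradient boosting of the Cox partial likelihood
# (Breslow ties); base learner = simple least-squares on one feature
fit_bglm_cox <- function(x, time, event, params) {
  n <- nrow(x)
  ord <- order(time)
  xo <- x[ord, , drop = FALSE]
  to <- time[ord]
  ev <- event[ord]
  beta <- numeric(ncol(x))
  eta <- numeric(n)
  xss <- colSums(xo^2)
  ok <- xss > 1e-12
  for (m in seq_len(params$mstop)) {
    ee <- exp(eta - max(eta))
    s0 <- rev(cumsum(rev(ee))) # sum over risk set at each ordered time
    cum <- cumsum(ifelse(ev == 1, 1 / s0, 0))
    grad <- ev - ee * cum # d logPL / d eta
    num <- as.numeric(crossprod(xo, grad))
    score <- ifelse(ok, num^2 / xss, 0)
    f <- which.max(score)
    if (score[f] <= 0) break
    step <- params$nu * num[f] / xss[f]
    beta[f] <- beta[f] + step
    eta <- eta + step * xo[, f]
  }
  list(coef = beta)
}

fit_xgb_cox <- function(x, time, event, params, seed) {
  lab <- ifelse(event == 1, time, -time)
  dm <- xgboost::xgb.DMatrix(x, label = lab)
  xgboost::xgb.train(
    params = list(
      objective = "survival:cox", eta = params$eta,
      max_depth = params$max_depth, nthread = 1, seed = seed
    ),
    data = dm, nrounds = params$nrounds, verbose = 0
  )
}

fit_xgb_aft <- function(x, time, event, params, seed) {
  dm <- xgboost::xgb.DMatrix(x)
  xgboost::setinfo(dm, "label_lower_bound", time)
  xgboost::setinfo(dm, "label_upper_bound", ifelse(event == 1, time, Inf))
  xgboost::xgb.train(
    params = list(
      objective = "survival:aft", aft_loss_distribution = "extreme",
      aft_loss_distribution_scale = 1.0, eta = params$eta,
      max_depth = params$max_depth, nthread = 1, seed = seed
    ),
    data = dm, nrounds = params$nrounds, verbose = 0
  )
}

fit_ranger_surv <- function(x, time, event, params, seed, splitrule) {
  df <- as.data.frame(x)
  df$.time <- time
  df$.event <- event
  ranger::ranger(
    survival::Surv(.time, .event) ~ .,
    data = df,
    num.trees = params$num_trees, min.node.size = params$min_node_size,
    splitrule = splitrule, seed = seed, num.threads = 1
  )
}
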