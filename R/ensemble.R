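#' Random-search hyper-parameter optimisation
#'
#' Samples `budget` configurations (signature size `k` in 1..10 plus the
#' learner-specific grid) and scores each by the mean out-of-bag Harrell
#' C-index over bootstrap fits on the exploratory rows. Deterministic given
#' `seed`.
#'
#' @param selector,learner the model combination.
#' @param table preprocessed exploratory feature tibble.
#' @param outcomes outcome tibble (`patient_id`, `time_months`, `event`).
#' @param ranking a [rank_features()] result for this selector.
#' @param budget number of sampled configurations (>= 1).
#' @param n_bootstrap bootstrap fits per configuration.
#' @param seed integer seed.
#' @return A list: `k`, `params`, `score` (OOB C-index), `trace` tibble.
#' @export
tune_hyperparams <- function(selector, learner, table, outcomes, ranking,
                             budget = 10, n_bootstrap = 25, seed = 1L) {
  selector <- match.arg(selector, SELECTORS)
  learner <- match.arg(learner, LEARNERS)
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  grid <- hyperparam_grid(learner)
  k_max <- min(10L, nrow(ranking))
  seeds <- derive_seeds(seed, budget)
  oc <- outcomes[match(table$patient_id, outcomes$patient_id), ]
  x_all <- as.matrix(table[, ranking$feature, drop = FALSE])
  n <- nrow(x_all)
  trace <- list()
  best <- NULL
  for (t in seq_len(budget)) {
    cfg <- with_local_seed(seeds[t], {
      c(
        list(k = sample.int(k_max, 1)),
        lapply(grid, function(vals) sample(vals, 1))
      )
    })
    feats <- ranking$feature[seq_len(cfg$k)]
    x <- x_all[, feats, drop = FALSE]
    bseeds <- derive_seeds(seeds[t], n_bootstrap)
    cvals <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- with_local_seed(bseeds[b], sample.int(n, n, replace = TRUE))
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < 5 || sum(oc$event[idx]) == 0) {
        return(NA_real_)
      }
      fit <- tryCatch(
        fit_learner(learner, x[idx, , drop = FALSE], oc$time_months[idx],
          oc$event[idx],
          params = cfg[names(cfg) != "k"], seed = bseeds[b]
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(NA_real_)
      }
      r <- predict_risk(fit, x[oob, , drop = FALSE])
      tryCatch(
        concordance_index(r, oc$time_months[oob], oc$event[oob]),
        error = function(e) NA_real_
      )
    }, numeric(1))
    score <- mean(cvals, na.rm = TRUE)
    trace[[t]] <- tibble::as_tibble(c(cfg, list(score = score)))
    if (is.null(best) || (is.finite(score) && score > best$score)) {
      best <- list(
        k = cfg$k, params = cfg[names(cfg) != "k"], score = score
      )
    }
  }
  best$trace <- dplyr::bind_rows(trace)
  best
}

#' Train a bootstrap ensemble of survival models
#'
#' Fits `n_bootstrap` copies of the learner on bootstrap resamples (with
#' replacement, full exploratory size) of the supplied rows, restricted to
#' the signature features. Bootstrap fits that fail (non-convergence,
#' all-censored resample) are dropped with a log record; training errors out
#' only when more than half the fits fail.
#'
#' @param selector,learner the model combination.
#' @param signature character vector of (meta-)feature names, best first.
#' @param hyperparams named list of learner hyper-parameters.
#' @param table preprocessed exploratory feature tibble.
#' @param outcomes outcome tibble.
#' @param n_bootstrap ensemble size B.
#' @param seed integer seed.
#' @return An object of class `rimcore_ensemble`.
#' @export
train_ensemble <- function(selector, learner, signature, hyperparams = list(),
                           table, outcomes, n_bootstrap = 1000, seed = 1L) {
  selector <- match.arg(selector, SELECTORS)
  learner <- match.arg(learner, LEARNERS)
  if (!all(signature %in% names(table))) {
    stop("signature features missing from table", call. = FALSE)
  }
  oc <- outcomes[match(table$patient_id, outcomes$patient_id), ]
  x <- as.matrix(table[, signature, drop = FALSE])
  n <- nrow(x)
  seeds <- derive_seeds(seed, n_bootstrap)
  fits <- vector("list", n_bootstrap)
  failed <- 0L
  for (b in seq_len(n_bootstrap)) {
    idx <- with_local_seed(seeds[b], sample.int(n, n, replace = TRUE))
    if (sum(oc$event[idx]) == 0) {
      rc_log("train_ensemble: bootstrap %d all-censored, dropped", b)
      failed <- failed + 1L
      next
    }
    res <- tryCatch(
      fit_learner(learner, x[idx, , drop = FALSE], oc$time_months[idx],
        oc$event[idx],
        params = hyperparams, seed = seeds[b]
      ),
      error = function(e) {
        rc_log("train_ensemble: bootstrap %d failed (%s)", b, conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) failed <- failed + 1L else fits[[b]] <- res
  }
  fits <- purrr::compact(fits)
  if (length(fits) < n_bootstrap / 2) {
    stop("more than half of the bootstrap fits failed", call. = FALSE)
  }
  structure(
    list(
      selector = selector, learner = learner, signature = signature,
      hyperparams = hyperparams, fits = fits,
      n_bootstrap = n_bootstrap, n_fitted = length(fits), seed = seed
    ),
    class = "rimcore_ensemble"
  )
}

#' Ensemble risk prediction
#'
#' The per-patient risk is the unweighted mean of the risk scores of every
#' fitted bootstrap model; higher risk means higher hazard of loco-regional
#' recurrence.
#'
#' @param model a [train_ensemble()] result.
#' @param table preprocessed feature tibble containing the signature
#'   columns and `patient_id`.
#' @return A tibble `patient_id`, `risk`.
#' @export
ensemble_predict <- function(model, table) {
  stopifnot(inherits(model, "rimcore_ensemble"))
  if (!all(model$signature %in% names(table))) {
    stop("signature columns missing from prediction rows", call. = FALSE)
  }
  x <- as.matrix(table[, model$signature, drop = FALSE])
  risks <- vapply(model$fits, predict_risk, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) risks <- matrix(risks, nrow = 1)
  tibble::tibble(
    patient_id = table$patient_id,
    risk = rowMeans(risks)
  )
}

#' @export
predict.rimcore_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}

#' @export
print.rimcore_ensemble <- function(x, ...) {
  cat(sprintf(
    "<rimcore_ensemble %s + %s, |signature| = %d, B = %d/%d>\n",
    x$selector, x$learner, length(x$signature), x$n_fitted, x$n_bootstrap
  ))
  cat("signature:", paste(utils::head(x$signature, 5), collapse = ", "),
    if (length(x$signature) > 5) "..." else "", "\n")
  invisible(x)
}

#' Broom-style accessors for ensembles
#'
#' `tidy()` returns one row per signature member with its selection order;
#' `glance()` returns a one-row model summary.
#'
#' @param x a `rimcore_ensemble`.
#' @param ... unused.
#' @export
tidy.rimcore_ensemble <- function(x, ...) {
  tibble::tibble(
    feature = x$signature,
    rank = seq_along(x$signature),
    selector = x$selector,
    learner = x$learner
  )
}

#' @rdname tidy.rimcore_ensemble
#' @export
glance.rimcore_ensemble <- function(x, ...) {
  tibble::tibble(
    selector = x$selector, learner = x$learner,
    signature_size = length(x$signature),
    n_bootstrap = x$n_bootstrap, n_fitted = x$n_fitted, seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' End-to-end risk model for one selector/learner combination
#'
#' Convenience wrapper chaining [preprocess_features()], [rank_features()],
#' [tune_hyperparams()] and [train_ensemble()] on the exploratory rows of a
#' feature table, returning everything needed to score new patients.
#'
#' @param features raw feature tibble (`patient_id` + feature columns).
#' @param outcomes outcome tibble.
#' @param exploratory_ids patient ids of the exploratory cohort.
#' @param selector,learner the model combination.
#' @param n_bootstrap_select,n_bootstrap_train bootstrap counts for feature
#'   selection and ensemble training.
#' @param tune_budget random-search budget; 0 skips tuning and uses the
#'   learner defaults with `k` = `default_k`.
#' @param default_k signature size when tuning is skipped.
#' @param seed master seed.
#' @return An object of class `rimcore_risk_model` containing the
#'   preprocessing transform, ranking, hyper-parameters and the fitted
#'   ensemble.
#' @export
train_risk_model <- function(features, outcomes, exploratory_ids,
                             selector = "spearman", learner = "cox",
                             n_bootstrap_select = 1000,
                             n_bootstrap_train = 1000,
                             tune_budget = 10, default_k = 5, seed = 1L) {
  selector <- match.arg(selector, SELECTORS)
  learner <- match.arg(learner, LEARNERS)
  seeds <- derive_seeds(seed, 3)
  prep <- preprocess_features(features, exploratory_ids)
  ex_tab <- prep$table[prep$table$patient_id %in% exploratory_ids, ]
  ranking <- rank_features(ex_tab, outcomes, selector,
    n_bootstrap = n_bootstrap_select, seed = seeds[1]
  )
  if (tune_budget >= 1) {
    tuned <- tune_hyperparams(selector, learner, ex_tab, outcomes, ranking,
      budget = tune_budget, seed = seeds[2]
    )
  } else {
    tuned <- list(
      k = min(default_k, nrow(ranking)),
      params = default_hyperparams(learner), score = NA_real_
    )
  }
  ens <- train_ensemble(
    selector, learner, ranking$feature[seq_len(tuned$k)],
    tuned$params, ex_tab, outcomes,
    n_bootstrap = n_bootstrap_train, seed = seeds[3]
  )
  structure(
    list(
      prep = prep, ranking = ranking, tuned = tuned, ensemble = ens,
      exploratory_ids = exploratory_ids, seed = seed
    ),
    class = "rimcore_risk_model"
  )
}

#' @export
predict.rimcore_risk_model <- function(object, newdata = NULL, ...) {
  tab <- if (is.null(newdata)) {
    object$prep$table
  } else {
    preprocess_apply(object$prep, newdata)
  }
  ensemble_predict(object$ensemble, tab)
}

#' @export
print.rimcore_risk_model <- function(x, ...) {
  cat(sprintf(
    "<rimcore_risk_model %s + %s, k = %d, OOB C = %s>\n",
    x$ensemble$selector, x$ensemble$learner, length(x$ensemble$signature),
    format(round(x$tuned$score, 3))
  ))
  invisible(x)
}
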