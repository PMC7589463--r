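#' Harrell's concordance index
#'
#' Over all patient pairs comparable under right censoring (the patient with
#' the shorter time experienced the event), the fraction in which the higher
#' predicted risk belongs to the earlier event, with tied risks counting
#' one half. 0.5 is random, 1.0 perfect.
#'
#' @param risk numeric risk scores (higher = worse).
#' @param time event/censoring times.
#' @param event event indicator (1 = event).
#' @return The concordance index in \[0, 1\].
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
    reverse = TRUE
  )
  npairs <- cc$count["concordant"] + cc$count["discordant"] +
    cc$count["tied.x"]
  if (npairs == 0) stop("no comparable pairs", call. = FALSE)
  as.numeric(cc$concordance)
}

#' Percentile bootstrap confidence interval for a per-cohort metric
#'
#' Resamples patients with replacement and returns the percentile interval
#' of the metric; degenerate resamples (where the metric errors, e.g. no
#' comparable pairs) are skipped with a log record.
#'
#' @param metric function of integer row indices returning a scalar.
#' @param n number of patients.
#' @param n_boot number of resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric, n, n_boot = 1000, level = 0.95, seed = 1L) {
  if (n < 10) stop("need at least 10 patients", call. = FALSE)
  seeds <- derive_seeds(seed, n_boot)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- with_local_seed(seeds[b], sample.int(n, n, replace = TRUE))
    tryCatch(metric(idx), error = function(e) NA_real_)
  }, numeric(1))
  bad <- sum(!is.finite(vals))
  if (bad > 0) rc_log("bootstrap_ci: %d degenerate resamples skipped", bad)
  q <- stats::quantile(vals[is.finite(vals)],
    c((1 - level) / 2, 1 - (1 - level) / 2),
    names = FALSE
  )
  c(lo = q[1], hi = q[2])
}

#' Median-risk patient stratification
#'
#' The cutoff is the median predicted risk of the exploratory cohort;
#' patients at or below the cutoff are "low" risk, above it "high". The
#' same cutoff is applied unchanged to the validation cohort.
#'
#' @param risk_explor exploratory risk scores.
#' @param risk_valid validation risk scores.
#' @return A list of class `rimcore_groups`: `cutoff`, `explor`, `valid`
#'   (factors `low`/`high`).
#' @export
stratify_risk <- function(risk_explor, risk_valid = numeric()) {
  if (length(risk_explor) == 0) stop("no exploratory risks", call. = FALSE)
  cutoff <- stats::median(risk_explor)
  grp <- function(r) {
    factor(ifelse(r <= cutoff, "low", "high"), levels = c("low", "high"))
  }
  gv <- grp(risk_valid)
  if (length(risk_valid) > 0 && length(unique(gv)) == 1) {
    rc_log("stratify_risk: all validation patients in one group")
    warning("all validation patients fall in one risk group", call. = FALSE)
  }
  structure(
    list(cutoff = cutoff, explor = grp(risk_explor), valid = gv),
    class = "rimcore_groups"
  )
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates with right censoring, one step function per
#' group, starting at probability 1.
#'
#' @param time,event outcome vectors.
#' @param group factor of group labels (optional; single curve if missing).
#' @return A tibble of class `rimcore_km`: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (is.null(group)) group <- factor(rep("all", length(time)))
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(levels(droplevels(group))[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble::tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, surv = fit$surv
  )
  class(out) <- c("rimcore_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' @param time,event outcome vectors.
#' @param group two-level factor.
#' @return The chi-square (1 df) p-value.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("need two non-empty groups", call. = FALSE)
  }
  sd_ <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = data.frame(time = time, event = event, group = group)
  )
  as.numeric(1 - stats::pchisq(sd_$chisq, df = 1))
}

#' Concordance by tumour-volume subgroup
#'
#' Recomputes the C-index separately for patients with tumours at or below
#' and above the volume threshold (20 cm^3 by default, roughly a 1.5 cm
#' spherical radius). Empty subgroups are omitted with a log record.
#'
#' @param risk,time,event validation vectors.
#' @param volumes_cm3 tumour volumes (cm^3), same order.
#' @param threshold split volume (cm^3).
#' @return A tibble: `subgroup`, `n`, `c_index`.
#' @export
subgroup_analysis <- function(risk, time, event, volumes_cm3,
                              threshold = 20) {
  stopifnot(length(volumes_cm3) == length(risk))
  sel <- list(
    small = volumes_cm3 <= threshold,
    large = volumes_cm3 > threshold
  )
  rows <- purrr::imap(sel, function(s, nm) {
    if (!any(s)) {
      rc_log("subgroup_analysis: subgroup '%s' empty, omitted", nm)
      return(NULL)
    }
    ci <- tryCatch(
      concordance_index(risk[s], time[s], event[s]),
      error = function(e) NA_real_
    )
    tibble::tibble(subgroup = nm, n = sum(s), c_index = ci)
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Paired comparison of two sub-volumes across model combinations
#'
#' Tests whether the mean C-index difference between two sub-volumes,
#' paired over the selector-by-learner combinations, could arise under a
#' sign-symmetric null: the observed mean difference is compared with its
#' distribution under random sign flips of the per-combination differences
#' (seeded; exhaustive up to `n_perm` draws). Two-sided p-value.
#'
#' @param c_a,c_b C-indices of the two sub-volumes, aligned by combination.
#' @param n_perm permutation draws.
#' @param seed integer seed.
#' @return A list: `statistic` (mean difference a - b), `p_value`, `n`.
#' @export
compare_subvolumes <- function(c_a, c_b, n_perm = 10000, seed = 1L) {
  stopifnot(length(c_a) == length(c_b))
  d <- c_a - c_b
  m <- length(d)
  if (m < 2) stop("need at least 2 combinations", call. = FALSE)
  obs <- mean(d)
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, n = m))
  }
  if (2^m <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  } else {
    signs <- with_local_seed(
      seed,
      matrix(sample(c(-1, 1), n_perm * m, replace = TRUE), ncol = m)
    )
  }
  null_stats <- as.numeric(signs %*% d) / m
  p <- mean(abs(null_stats) >= abs(obs) - 1e-12)
  list(statistic = obs, p_value = p, n = m)
}

#' Representative model combination for a sub-volume
#'
#' For each feature-selection method the median C-index over learners is
#' taken (and vice versa); the representative combination pairs the
#' selector whose median performance is closest to the median of selector
#' medians with the learner chosen analogously. Ties break
#' lexicographically.
#'
#' @param results tibble with columns `selector`, `learner`, `c_index`.
#' @return A list: `selector`, `learner`.
#' @export
select_representative <- function(results) {
  stopifnot(all(c("selector", "learner", "c_index") %in% names(results)))
  pick <- function(var) {
    med <- results |>
      dplyr::group_by(.data[[var]]) |>
      dplyr::summarise(m = stats::median(.data$c_index), .groups = "drop") |>
      dplyr::arrange(.data[[var]])
    target <- stats::median(med$m)
    med[[var]][order(abs(med$m - target), med[[var]])][1]
  }
  list(selector = pick("selector"), learner = pick("learner"))
}

#' Evaluate a fitted risk model on both cohorts
#'
#' Computes the C-index on the exploratory and validation cohorts, a
#' percentile-bootstrap confidence interval on the validation C-index,
#' median-risk stratification with a validation log-rank test, and the
#' tumour-volume subgroup C-indices.
#'
#' @param model a [train_risk_model()] fit.
#' @param features raw feature tibble (all patients).
#' @param outcomes outcome tibble.
#' @param cohorts tibble `patient_id`, `cohort` (`"exploratory"` /
#'   `"validation"`).
#' @param volumes_cm3 optional named vector (by patient id) for the
#'   subgroup analysis.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed integer seed.
#' @return A one-row tibble of class `rimcore_eval`.
#' @export
evaluate_model <- function(model, features, outcomes, cohorts,
                           volumes_cm3 = NULL, n_boot = 1000, seed = 1L) {
  pred <- stats::predict(model, features)
  dat <- pred |>
    dplyr::left_join(cohorts, by = "patient_id") |>
    dplyr::left_join(outcomes, by = "patient_id")
  ex <- dat[dat$cohort == "exploratory", ]
  va <- dat[dat$cohort == "validation", ]
  c_ex <- concordance_index(ex$risk, ex$time_months, ex$event)
  c_va <- concordance_index(va$risk, va$time_months, va$event)
  ci <- tryCatch(
    bootstrap_ci(
      function(idx) {
        concordance_index(va$risk[idx], va$time_months[idx], va$event[idx])
      },
      n = nrow(va), n_boot = n_boot, seed = seed
    ),
    error = function(e) {
      rc_log("evaluate_model: CI unavailable (%s)", conditionMessage(e))
      c(lo = NA_real_, hi = NA_real_)
    }
  )
  grp <- stratify_risk(ex$risk, va$risk)
  p_lr <- tryCatch(
    logrank_test(va$time_months, va$event, grp$valid),
    error = function(e) NA_real_
  )
  sub <- NULL
  if (!is.null(volumes_cm3)) {
    vv <- volumes_cm3[va$patient_id]
    sub <- subgroup_analysis(va$risk, va$time_months, va$event, vv)
  }
  out <- tibble::tibble(
    selector = model$ensemble$selector, learner = model$ensemble$learner,
    c_index_explor = c_ex, c_index_valid = c_va,
    ci_lo = ci["lo"], ci_hi = ci["hi"],
    logrank_p = p_lr, cutoff = grp$cutoff,
    c_index_small = if (!is.null(sub) && "small" %in% sub$subgroup) {
      sub$c_index[sub$subgroup == "small"]
    } else {
      NA_real_
    },
    c_index_large = if (!is.null(sub) && "large" %in% sub$subgroup) {
      sub$c_index[sub$subgroup == "large"]
    } else {
      NA_real_
    }
  )
  class(out) <- c("rimcore_eval", class(out))
  out
}
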