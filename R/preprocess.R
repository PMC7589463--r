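feature_cols <- function(table, id_cols = c("patient_id", "roi", "cohort")) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))], id_cols)
}

#' Normalise features and collapse correlated clusters into meta-features
#'
#' Every feature is z-scored with the mean and standard deviation of the
#' exploratory rows only (validation rows are transformed with the same
#' statistics — no leakage). Zero-variance features are dropped (logged).
#' Features are then clustered by complete-linkage hierarchical clustering
#' on `1 - |Spearman rho|` over exploratory rows; clusters whose members all
#' correlate at `|rho| >=` `cor_threshold` are replaced by the mean of their
#' member z-scores, a meta-feature named after the cluster's first member.
#'
#' @param table feature tibble with a `patient_id` column.
#' @param exploratory_ids patient ids forming the exploratory cohort.
#' @param cor_threshold absolute Spearman correlation defining a cluster.
#' @return A list of class `rimcore_preproc`: `table` (transformed, all
#'   rows), `cluster_map` (tibble `feature` -> `meta`), `stats` (per-feature
#'   exploratory mean/sd), `features` (output feature names).
#' @export
preprocess_features <- function(table, exploratory_ids, cor_threshold = 0.90) {
  feats <- feature_cols(table)
  ex <- table$patient_id %in% exploratory_ids
  if (sum(ex) < 2) stop("fewer than 2 exploratory rows", call. = FALSE)
  xm <- as.matrix(table[, feats])
  mu <- colMeans(xm[ex, , drop = FALSE])
  sd_ <- apply(xm[ex, , drop = FALSE], 2, stats::sd)
  drop <- sd_ <= 1e-12 | !is.finite(sd_)
  if (any(drop)) {
    rc_log(
      "preprocess: dropped %d zero-variance features (%s%s)", sum(drop),
      paste(utils::head(feats[drop], 3), collapse = ", "),
      if (sum(drop) > 3) ", ..." else ""
    )
  }
  feats <- feats[!drop]
  xm <- xm[, feats, drop = FALSE]
  z <- sweep(sweep(xm, 2, mu[feats]), 2, sd_[feats], `/`)

  # cluster on exploratory correlations only
  cl <- rep(seq_along(feats), 1)
  if (length(feats) >= 2) {
    rho <- suppressWarnings(
      stats::cor(z[ex, , drop = FALSE], method = "spearman")
    )
    rho[!is.finite(rho)] <- 0
    dd <- stats::as.dist(1 - abs(rho))
    hc <- stats::hclust(dd, method = "complete")
    cl <- stats::cutree(hc, h = 1 - cor_threshold)
  }
  out <- tibble::as_tibble(table[, intersect(
    c("patient_id", "roi", "cohort"), names(table)
  )])
  map_rows <- list()
  new_cols <- list()
  for (g in sort(unique(cl))) {
    members <- sort(feats[cl == g])
    if (length(members) == 1) {
      nm <- members
      val <- z[, members]
    } else {
      nm <- paste0("meta_", members[1])
      val <- rowMeans(z[, members, drop = FALSE])
    }
    new_cols[[nm]] <- as.numeric(val)
    map_rows[[length(map_rows) + 1]] <- tibble::tibble(
      feature = members, meta = nm
    )
  }
  res <- dplyr::bind_cols(out, tibble::as_tibble(new_cols))
  structure(
    list(
      table = res,
      cluster_map = dplyr::bind_rows(map_rows),
      stats = tibble::tibble(
        feature = feats, mean = mu[feats], sd = sd_[feats]
      ),
      features = names(new_cols)
    ),
    class = "rimcore_preproc"
  )
}

#' Apply a fitted preprocessing transform to new feature rows
#'
#' @param prep a [preprocess_features()] result.
#' @param table raw feature tibble (same feature columns).
#' @return Transformed tibble in the preprocessed feature space.
#' @export
preprocess_apply <- function(prep, table) {
  stopifnot(inherits(prep, "rimcore_preproc"))
  xm <- as.matrix(table[, prep$stats$feature])
  z <- sweep(sweep(xm, 2, prep$stats$mean), 2, prep$stats$sd, `/`)
  out <- tibble::as_tibble(table[, intersect(
    c("patient_id", "roi", "cohort"), names(table)
  )])
  cols <- lapply(prep$features, function(nm) {
    members <- prep$cluster_map$feature[prep$cluster_map$meta == nm]
    if (length(members) == 1) {
      as.numeric(z[, members])
    } else {
      rowMeans(z[, members, drop = FALSE])
    }
  })
  names(cols) <- prep$features
  dplyr::bind_cols(out, tibble::as_tibble(cols))
}

# mutual information (bits) between two discrete vectors
mi_disc <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  pp <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / pp[nz]))
}

# equal-frequency binning into up to `bins` levels
ef_bin <- function(x, bins = 4) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) {
    return(rep(1L, length(x)))
  }
  as.integer(cut(x, br, include.lowest = TRUE))
}

#' Bootstrap-aggregated feature ranking
#'
#' Scores features on `n_bootstrap` resamples of the supplied (exploratory)
#' rows and aggregates by mean rank. Selectors: `"spearman"` (absolute
#' Spearman correlation between feature and event time among event
#' patients), `"mim"` (mutual information between the 4-bin equal-frequency
#' binned feature and the event indicator), `"mifs"` / `"mrmr"` (greedy
#' forward mutual-information schemes; MIFS subtracts the summed redundancy
#' with already-selected features at penalty beta = 1, MRMR subtracts the
#' mean redundancy), and `"rfvi"` (permutation importance of a random
#' survival forest). Ties in the final ordering break by feature name.
#'
#' @param table preprocessed feature tibble (exploratory rows).
#' @param outcomes tibble with `patient_id`, `time_months`, `event`.
#' @param selector one of `"spearman"`, `"mim"`, `"mifs"`, `"mrmr"`,
#'   `"rfvi"`.
#' @param n_bootstrap number of bootstrap resamples.
#' @param seed integer seed.
#' @param greedy_depth how many features the greedy schemes order before
#'   assigning the remaining features a shared tail rank.
#' @param rf_trees trees per forest for `"rfvi"`.
#' @return A tibble `feature`, `mean_rank`, ordered best-first.
#' @export
rank_features <- function(table, outcomes, selector = SELECTORS,
                          n_bootstrap = 1000, seed = 1L, greedy_depth = 15,
                          rf_trees = 100) {
  selector <- match.arg(selector)
  feats <- feature_cols(table)
  x <- as.matrix(table[, feats])
  oc <- outcomes[match(table$patient_id, outcomes$patient_id), ]
  stopifnot(!anyNA(oc$time_months))
  n <- nrow(x)
  nf <- length(feats)
  seeds <- derive_seeds(seed, n_bootstrap)
  rank_sum <- numeric(nf)
  for (b in seq_len(n_bootstrap)) {
    idx <- with_local_seed(seeds[b], sample.int(n, n, replace = TRUE))
    xb <- x[idx, , drop = FALSE]
    tb <- oc$time_months[idx]
    eb <- oc$event[idx]
    rk <- switch(selector,
      spearman = {
        ev <- eb == 1
        sc <- if (sum(ev) >= 3) {
          abs(suppressWarnings(stats::cor(xb[ev, , drop = FALSE], tb[ev],
            method = "spearman"
          )))[, 1]
        } else {
          rep(0, nf)
        }
        sc[!is.finite(sc)] <- 0
        rank(-sc, ties.method = "average")
      },
      mim = {
        bins <- apply(xb, 2, ef_bin)
        sc <- apply(bins, 2, mi_disc, b = eb)
        rank(-sc, ties.method = "average")
      },
      mifs = greedy_mi_rank(xb, eb, beta = 1, depth = greedy_depth),
      mrmr = greedy_mi_rank(xb, eb, beta = NA, depth = greedy_depth),
      rfvi = {
        fit <- ranger::ranger(
          survival::Surv(.time, .event) ~ .,
          data = data.frame(xb, .time = tb, .event = eb,
            check.names = FALSE),
          num.trees = rf_trees, importance = "permutation",
          seed = seeds[b], num.threads = 1
        )
        rank(-fit$variable.importance, ties.method = "average")
      }
    )
    rank_sum <- rank_sum + rk
  }
  res <- tibble::tibble(feature = feats, mean_rank = rank_sum / n_bootstrap)
  dplyr::arrange(res, .data$mean_rank, .data$feature)
}

# greedy forward MI selection; beta = NA means MRMR (mean redundancy)
greedy_mi_rank <- function(x, event, beta, depth) {
  nf <- ncol(x)
  bins <- apply(x, 2, ef_bin)
  rel <- apply(bins, 2, mi_disc, b = event)
  depth <- min(depth, nf)
  selected <- integer(0)
  remaining <- seq_len(nf)
  red_sum <- numeric(nf)
  rk <- numeric(nf)
  for (step in seq_len(depth)) {
    score <- if (length(selected) == 0) {
      rel[remaining]
    } else if (is.na(beta)) {
      rel[remaining] - red_sum[remaining] / length(selected)
    } else {
      rel[remaining] - beta * red_sum[remaining]
    }
    pick <- remaining[which.max(score)]
    rk[pick] <- step
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    add <- vapply(
      remaining,
      function(f) mi_disc(bins[, f], bins[, pick]),
      numeric(1)
    )
    red_sum[remaining] <- red_sum[remaining] + add
  }
  if (length(remaining)) {
    rk[remaining] <- depth + (nf - depth + 1) / 2 # shared tail rank
  }
  rk
}
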