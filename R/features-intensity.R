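#' Fixed-bin-number grey-level discretisation
#'
#' Maps in-ROI intensities to consecutive integer levels `1..n_bins` over
#' their own `[min, max]` range (fixed bin number). A constant ROI maps every
#' voxel to level 1.
#'
#' @param intensities numeric vector of in-ROI intensities.
#' @param n_bins number of grey levels (>= 2).
#' @return A list: `levels` (integer vector), `n_levels`, `edges`.
#' @export
discretise <- function(intensities, n_bins = 32) {
  if (length(intensities) == 0) stop("empty ROI", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  lo <- min(intensities)
  hi <- max(intensities)
  if (hi - lo <= 0) {
    lev <- rep.int(1L, length(intensities))
    return(list(
      levels = lev, n_levels = as.integer(n_bins),
      edges = c(lo, hi)
    ))
  }
  lev <- pmin(
    as.integer(floor(n_bins * (intensities - lo) / (hi - lo))) + 1L,
    as.integer(n_bins)
  )
  list(
    levels = lev, n_levels = as.integer(n_bins),
    edges = seq(lo, hi, length.out = n_bins + 1)
  )
}

pctl <- function(x, p) as.numeric(stats::quantile(x, p, type = 7, names = FALSE))

# the 18-item intensity-statistics family on a value vector
stat_block <- function(x, prefix) {
  n <- length(x)
  mu <- mean(x)
  va <- mean((x - mu)^2) # population variance
  md <- stats::median(x)
  p10 <- pctl(x, 0.10)
  p25 <- pctl(x, 0.25)
  p75 <- pctl(x, 0.75)
  p90 <- pctl(x, 0.90)
  degenerate <- va <= 0
  if (degenerate) rc_log("%s: zero variance, moment ratios set to 0", prefix)
  sk <- if (degenerate) 0 else mean((x - mu)^3) / va^1.5
  ku <- if (degenerate) 0 else mean((x - mu)^4) / va^2 - 3
  cov <- if (degenerate) 0 else sqrt(va) / mu
  if (!degenerate && mu == 0) {
    rc_log("%s: zero mean, coefficient of variation set to 0", prefix)
    cov <- 0
  }
  xr <- x[x >= p10 & x <= p90]
  qcod <- if (p75 + p25 == 0) 0 else (p75 - p25) / (p75 + p25)
  out <- c(
    mean = mu, var = va, skew = sk, kurt = ku, median = md,
    min = min(x), p10 = p10, p90 = p90, max = max(x),
    iqr = p75 - p25, range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    madr = if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    medad = mean(abs(x - md)),
    cov = cov, qcod = qcod,
    energy = sum(x^2), rms = sqrt(mean(x^2))
  )
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Intensity-statistics features (18)
#'
#' Mean, population variance, skewness, excess kurtosis, median, minimum,
#' 10th/90th percentile, maximum, interquartile range, range, mean absolute
#' deviation, robust MAD (over the 10-90 percentile window), median absolute
#' deviation, coefficient of variation, quartile coefficient of dispersion,
#' energy and root mean square. Moment ratios on zero-variance input fall
#' back to 0 (logged).
#'
#' @param intensities numeric vector of in-ROI intensities.
#' @return Named numeric vector of length 18.
#' @export
statistical_features <- function(intensities) {
  if (length(intensities) < 1) stop("empty ROI", call. = FALSE)
  stat_block(intensities, "stat")
}

#' Histogram, intensity-volume-histogram and peak features (38)
#'
#' The 23-item discretised intensity-histogram family (histogram analogues
#' of the statistics plus mode, entropy, uniformity and the four histogram
#' gradient features), the 13-item intensity-volume-histogram family
#' computed on the continuous in-ROI intensities (volume fractions at the
#' 10/25/50/75/90% intensity fractions, intensities at the corresponding
#' volume fractions, the V10-V90 and I10-I90 differences, and the IVH area)
#' and the local and global intensity peaks (mean intensity in a 1 cm^3
#' sphere). If no image context is supplied the peaks degrade to the ROI
#' maximum (logged).
#'
#' @param droi a [discretise()] result.
#' @param intensities the continuous in-ROI intensities.
#' @param image,mask optional aligned [image_volume()] / [roi_mask()] pair
#'   used for the spherical peak features.
#' @return Named numeric vector of length 38.
#' @export
histogram_features <- function(droi, intensities, image = NULL, mask = NULL) {
  lev <- droi$levels
  ng <- droi$n_levels
  n <- length(lev)
  tab <- tabulate(lev, nbins = ng)
  p <- tab / n

  ih <- stat_block(lev, "ih")
  ih <- ih[!names(ih) %in% c("ih_energy", "ih_rms")]
  mode_lev <- which(tab == max(tab))[1]
  pos <- p[p > 0]
  grad <- (c(tab[-1], tab[ng]) - c(tab[1], tab[-ng])) / 2
  grad[1] <- tab[2] - tab[1]
  grad[ng] <- tab[ng] - tab[ng - 1]
  ih <- c(
    ih,
    ih_mode = as.numeric(mode_lev),
    ih_entropy = -sum(pos * log2(pos)),
    ih_uniformity = sum(p^2),
    ih_max_grad = max(grad),
    ih_max_grad_level = as.numeric(which.max(grad)),
    ih_min_grad = min(grad),
    ih_min_grad_level = as.numeric(which.min(grad))
  )

  ivh <- ivh_block(intensities)

  if (!is.null(image) && !is.null(mask)) {
    pk <- .cpp_peaks(
      as.numeric(as_plain(image)), as.integer(as_plain(mask)),
      as.integer(dim(image)), 6.2035, spacing(image)[1]
    )
  } else {
    rc_log("histogram_features: no image context, peak features degraded")
    pk <- c(max(intensities), max(intensities))
  }
  c(ih, ivh, loc_peak_local = pk[1], loc_peak_global = pk[2])
}

ivh_block <- function(x) {
  n <- length(x)
  lo <- min(x)
  hi <- max(x)
  xs <- sort(x)
  # V(b) = fraction of voxels with intensity >= b, via binary search
  vf <- function(b) (n - findInterval(b, xs, left.open = TRUE)) / n
  if (hi - lo <= 0) {
    v <- rep(1, 5)
    i <- rep(lo, 5)
    auc <- 1
  } else {
    gam <- c(0.10, 0.25, 0.50, 0.75, 0.90)
    v <- vf(lo + gam * (hi - lo))
    ux <- unique(xs)
    vu <- vf(ux)
    i <- vapply(c(0.10, 0.25, 0.50, 0.75, 0.90), function(fr) {
      ok <- ux[vu <= fr]
      if (length(ok)) min(ok) else hi
    }, numeric(1))
    auc <- mean(vf(seq(lo, hi, length.out = 1000)))
  }
  c(
    ivh_v10 = v[1], ivh_v25 = v[2], ivh_v50 = v[3], ivh_v75 = v[4],
    ivh_v90 = v[5],
    ivh_i10 = i[1], ivh_i25 = i[2], ivh_i50 = i[3], ivh_i75 = i[4],
    ivh_i90 = i[5],
    ivh_diff_v10_v90 = v[1] - v[5],
    ivh_diff_i10_i90 = i[1] - i[5],
    ivh_auc = auc
  )
}
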