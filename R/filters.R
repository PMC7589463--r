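# Coiflet-1 analysis filters (6 taps). The high-pass is the quadrature
# mirror of the low-pass; taps sum to sqrt(2) / 0 respectively.
COIF1_LO <- c(
  -0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
  0.8525720202116004, 0.3378976624574818, -0.07273261951252645
)
COIF1_HI <- c(
  0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
  0.3848648468648578, 0.07273261951252645, -0.015655728135791993
)

conv_axis <- function(values, kernel, axis,
                      origin = (length(kernel) - 1L) %/% 2L) {
  d <- dim(values)
  array(
    .cpp_conv_axis(
      as.numeric(values), as.integer(d), as.numeric(kernel),
      as.integer(axis), as.integer(origin)
    ),
    dim = d
  )
}

#' Stationary coiflet-1 wavelet filter bank
#'
#' Single-level undecimated (stationary) 3D wavelet decomposition with the
#' coiflet-1 filter pair, applying a low- (`L`) or high-pass (`H`) filter
#' along each spatial axis. All eight `{L,H}^3` combinations are returned,
#' including `LLL` and `HHH`, each on the input grid. Boundaries are handled
#' by symmetric (mirror) padding.
#'
#' @param image an [image_volume()] on an isotropic grid.
#' @return A named list of eight [image_volume()] objects
#'   (`LLL`, `LLH`, ..., `HHH`; letters ordered by axis x, y, z).
#' @export
wavelet_bank <- function(image) {
  d <- dim(image)
  if (any(d < length(COIF1_LO))) {
    stop("image smaller than the wavelet filter support", call. = FALSE)
  }
  vals <- as_plain(image)
  sp <- spacing(image)
  combos <- expand.grid(
    x = c("L", "H"), y = c("L", "H"), z = c("L", "H"),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(combos)), function(r) {
    res <- vals
    for (axis in 1:3) {
      k <- if (combos[r, axis] == "L") COIF1_LO else COIF1_HI
      res <- conv_axis(res, k, axis)
    }
    image_volume(res, sp, attr(image, "origin_mm"))
  })
  names(out) <- paste0(combos$x, combos$y, combos$z)
  out[order(names(out))]
}

# sampled Gaussian and its second derivative, radius 4 sigma
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_d2_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- (x^2 / sigma^4 - 1 / sigma^2) * g
  k - mean(k) # zero DC response despite truncation
}

#' Multi-scale Laplacian-of-Gaussian image
#'
#' Computes the scale-normalised LoG response `sigma^2 * Laplacian(G_sigma *
#' I)` at each kernel width and combines the per-scale responses into one
#' image by their voxelwise mean. The Laplacian is assembled from separable
#' Gaussian second-derivative kernels; boundaries are mirrored.
#'
#' @param image an [image_volume()] on an isotropic grid.
#' @param sigmas_mm Gaussian kernel widths in mm.
#' @param combine how to merge scales: `"mean"` (default) or `"stack"` to
#'   return the per-scale list.
#' @return An [image_volume()] (or a list of them for `"stack"`).
#' @export
log_filter <- function(image, sigmas_mm = c(1, 2, 3, 5, 6),
                       combine = c("mean", "stack")) {
  combine <- match.arg(combine)
  if (length(sigmas_mm) == 0) stop("empty sigma list", call. = FALSE)
  if (any(sigmas_mm <= 0)) stop("sigmas must be > 0", call. = FALSE)
  if (!is_isotropic(image)) stop("image grid must be isotropic", call. = FALSE)
  sp <- spacing(image)[1]
  vals <- as_plain(image)
  per_scale <- lapply(sigmas_mm, function(s_mm) {
    s <- s_mm / sp # voxels
    g <- gauss_kernel(s)
    g2 <- gauss_d2_kernel(s)
    resp <- array(0, dim = dim(vals))
    for (axis in 1:3) {
      r <- vals
      for (ax2 in 1:3) {
        r <- conv_axis(r, if (ax2 == axis) g2 else g, ax2)
      }
      resp <- resp + r
    }
    resp * s^2 # scale-normalised, in voxel units
  })
  if (combine == "stack") {
    return(lapply(per_scale, image_volume,
      spacing_mm = spacing(image), origin_mm = attr(image, "origin_mm")
    ))
  }
  image_volume(
    Reduce(`+`, per_scale) / length(per_scale),
    spacing(image), attr(image, "origin_mm")
  )
}

#' Build the full 10-image transform stack for a patient
#'
#' The base image plus its nine filtered companions: eight stationary
#' coiflet-1 wavelet combinations and one multi-scale LoG image. Filtering is
#' applied on the full grid before any masking, so HU-defined re-segmentation
#' stays meaningful (it is always taken on the base image).
#'
#' @param image base [image_volume()] (isotropic).
#' @param sigmas_mm LoG kernel widths, passed to [log_filter()].
#' @return A named list of 10 [image_volume()]s: `base`, `wav_LLL`, ...,
#'   `wav_HHH`, `log`.
#' @export
filter_bank <- function(image, sigmas_mm = c(1, 2, 3, 5, 6)) {
  wav <- wavelet_bank(image)
  names(wav) <- paste0("wav_", names(wav))
  c(
    list(base = image),
    wav,
    list(log = log_filter(image, sigmas_mm))
  )
}
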