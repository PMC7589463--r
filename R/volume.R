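#' 3D image volume and ROI mask containers
#'
#' An `image_volume` is a 3D numeric array of CT-like intensities (Hounsfield
#' units) carrying per-axis voxel spacing and origin in millimetres. An
#' `roi_mask` is a 0/1 integer array on the same grid, labelled with the
#' sub-volume role it represents (`"entire"`, `"rim"`, `"core"`,
#' `"rim+ext"`, ...).
#'
#' @param values 3D numeric array.
#' @param spacing_mm voxel spacing in mm; scalar or length-3 (x, y, z).
#' @param origin_mm position of the first voxel centre in mm; length-3.
#' @return An object of class `rimcore_volume` (array with `spacing_mm` and
#'   `origin_mm` attributes).
#' @export
image_volume <- function(values, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be positive and finite", call. = FALSE)
  }
  structure(values,
    spacing_mm = spacing_mm,
    origin_mm = rep_len(as.numeric(origin_mm), 3L),
    class = "rimcore_volume"
  )
}

#' @param role sub-volume role label.
#' @rdname image_volume
#' @export
roi_mask <- function(values, spacing_mm = 1, origin_mm = c(0, 0, 0),
                     role = "entire") {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  vals <- as.integer(values != 0)
  dim(vals) <- dim(values)
  out <- image_volume(vals, spacing_mm, origin_mm)
  class(out) <- "rimcore_mask"
  attr(out, "role") <- role
  out
}

#' @export
print.rimcore_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_volume %d x %d x %d, spacing %s mm, range [%.1f, %.1f]>\n",
    d[1], d[2], d[3], paste(signif(spacing(x), 3), collapse = "x"),
    min(x), max(x)
  ))
  invisible(x)
}

#' @export
print.rimcore_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<roi_mask '%s' %d x %d x %d, %d voxels, %.2f cm3>\n",
    attr(x, "role"), d[1], d[2], d[3], sum(x), mask_volume_cm3(x)
  ))
  invisible(x)
}

spacing <- function(x) attr(x, "spacing_mm") %||% c(1, 1, 1)

is_isotropic <- function(x, tol = 1e-8) {
  s <- spacing(x)
  diff(range(s)) <= tol * max(s)
}

assert_aligned <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask grids differ in shape", call. = FALSE)
  }
  if (max(abs(spacing(image) - spacing(mask))) > 1e-8) {
    stop("image and mask voxel spacings differ", call. = FALSE)
  }
  invisible(TRUE)
}

# strip class/attrs for raw array maths
as_plain <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}
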