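#' Resample an image/mask pair to isotropic voxel spacing
#'
#' The image is interpolated with separable natural cubic splines (which
#' reproduce affine intensity profiles exactly); the mask is interpolated
#' trilinearly and thresholded at 0.5. Output voxel centres start at the
#' input origin and step by `target_mm`, covering the input extent.
#'
#' @param image an [image_volume()].
#' @param mask an [roi_mask()] aligned with `image`.
#' @param target_mm target isotropic spacing (mm).
#' @return A list with resampled `image` and `mask`.
#' @export
resample_isotropic <- function(image, mask, target_mm = 1.0) {
  if (!is.numeric(target_mm) || target_mm <= 0) {
    stop("`target_mm` must be positive", call. = FALSE)
  }
  assert_aligned(image, mask)
  sp <- spacing(image)
  if (max(abs(sp - target_mm)) < 1e-9) {
    return(list(image = image, mask = mask))
  }
  role <- attr(mask, "role")
  img <- resample_grid(as_plain(image), sp, target_mm, linear = FALSE)
  msk <- resample_grid(as_plain(mask) + 0, sp, target_mm, linear = TRUE)
  msk <- array(as.integer(msk >= 0.5), dim = dim(msk))
  list(
    image = image_volume(img, target_mm, attr(image, "origin_mm")),
    mask = roi_mask(msk, target_mm, attr(image, "origin_mm"), role = role)
  )
}

# separable 1D interpolation along each axis in turn
resample_grid <- function(values, spacing_mm, target_mm, linear) {
  for (axis in 1:3) {
    d <- dim(values)
    n_in <- d[axis]
    extent <- (n_in - 1) * spacing_mm[axis]
    xs_in <- seq(0, extent, by = spacing_mm[axis])
    xs_out <- seq(0, extent + 1e-9, by = target_mm)
    if (n_in == 1L) {
      xs_out <- 0
    }
    n_out <- length(xs_out)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(values, perm), nrow = n_in)
    res <- if (n_in == 1L) {
      m
    } else if (linear) {
      apply(m, 2, function(v) stats::approx(xs_in, v, xout = xs_out)$y)
    } else {
      apply(m, 2, function(v) {
        stats::spline(xs_in, v, xout = xs_out, method = "natural")$y
      })
    }
    res <- array(res, dim = c(n_out, d[perm[2]], d[perm[3]]))
    values <- aperm(res, order(perm))
    spacing_mm[axis] <- target_mm
  }
  values
}

# squared Euclidean distance (voxel units) of mask voxels to the nearest
# background voxel centre; 0 outside the mask. Computed on the mask bounding
# box plus one voxel, which is exact for in-mask distances.
mask_edt_sq <- function(mask) {
  d <- dim(mask)
  m <- as_plain(mask)
  idx <- which(m > 0)
  out <- array(0, dim = d)
  if (length(idx) == 0) {
    return(out)
  }
  i <- (idx - 1) %% d[1] + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  lo <- pmax(c(min(i), min(j), min(k)) - 1L, 1L)
  hi <- pmin(c(max(i), max(j), max(k)) + 1L, d)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  arr <- .cpp_edt_sq(as.integer(sub), as.integer(ds))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    array(arr, dim = ds) * (sub > 0)
  out
}

#' Construct the tumour core by an inward margin
#'
#' The candidate core keeps every voxel whose Euclidean distance (exact
#' distance transform, voxel-centre metric) to the nearest background voxel
#' is at least `margin_mm`. When that candidate holds less than
#' `min_fraction` of the entire volume, the margin is relaxed to the largest
#' distance threshold whose super-level set reaches the floor (ties at the
#' threshold all included), so small tumours keep a usable core.
#'
#' @param mask an [roi_mask()] on an isotropic grid.
#' @param margin_mm inward margin (mm), >= 0.
#' @param min_fraction minimum core:entire volume fraction.
#' @return An [roi_mask()] with role `"core"` and attributes
#'   `core_fraction` and `margin_mm`.
#' @export
make_core <- function(mask, margin_mm, min_fraction = 0.40) {
  if (!is_isotropic(mask)) stop("mask grid must be isotropic", call. = FALSE)
  if (margin_mm < 0) stop("`margin_mm` must be >= 0", call. = FALSE)
  n_entire <- sum(mask)
  if (n_entire == 0) stop("empty mask", call. = FALSE)
  sp <- spacing(mask)[1]
  dist_mm2 <- mask_edt_sq(mask) * sp^2
  in_mask <- which(as_plain(mask) > 0)
  dv <- dist_mm2[in_mask]
  keep <- dv >= margin_mm^2
  if (sum(keep) / n_entire < min_fraction && n_entire >= 3) {
    # largest distance threshold whose super-level set reaches the floor;
    # ties at the threshold all included
    k0 <- ceiling(min_fraction * n_entire)
    thr <- sort(dv, decreasing = TRUE)[k0]
    keep <- dv >= thr
  }
  core <- array(FALSE, dim = dim(mask))
  core[in_mask[keep]] <- TRUE
  out <- roi_mask(array(as.integer(core), dim = dim(mask)), sp,
    attr(mask, "origin_mm"),
    role = sprintf("core(%g)", margin_mm)
  )
  attr(out, "core_fraction") <- sum(core) / n_entire
  attr(out, "margin_mm") <- margin_mm
  out
}

#' Tumour rim as the set difference entire minus core
#'
#' @param entire,core [roi_mask()] objects, `core` a subset of `entire`.
#' @return An [roi_mask()] with role `"rim"`.
#' @export
make_rim <- function(entire, core) {
  assert_aligned(entire, core)
  if (any(as_plain(core) > as_plain(entire))) {
    stop("`core` is not a subset of `entire`", call. = FALSE)
  }
  rim <- as_plain(entire) - as_plain(core)
  roi_mask(rim, spacing(entire)[1], attr(entire, "origin_mm"),
    role = sprintf("rim(%s)", attr(core, "margin_mm") %||% "?")
  )
}

#' Extend the rim outward into surrounding tissue
#'
#' Dilates the entire mask by `ext_mm` (background voxels whose distance to
#' the mask is at most `ext_mm`, by the same voxel-centre metric) and removes
#' the core. With `ext_mm = 0` this reduces exactly to [make_rim()]. If the
#' dilation reaches the grid boundary the extension is truncated and a
#' warning is recorded.
#'
#' @param entire,core [roi_mask()] objects.
#' @param ext_mm outward extension distance (mm), >= 0.
#' @return An [roi_mask()] with role `"rim+ext"`.
#' @export
extend_rim <- function(entire, core, ext_mm) {
  assert_aligned(entire, core)
  if (!is_isotropic(entire)) stop("grid must be isotropic", call. = FALSE)
  if (ext_mm < 0) stop("`ext_mm` must be >= 0", call. = FALSE)
  sp <- spacing(entire)[1]
  d <- dim(entire)
  # outward distance computed on the bounding box padded by the extension
  m <- as_plain(entire)
  idx <- which(m > 0)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  i <- (idx - 1) %% d[1] + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  pad <- ceiling(ext_mm / sp) + 1L
  lo <- pmax(c(min(i), min(j), min(k)) - pad, 1L)
  hi <- pmin(c(max(i), max(j), max(k)) + pad, d)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  inv <- array(1L - as.integer(sub), dim = ds)
  sub_d2 <- array(.cpp_edt_sq(inv, as.integer(ds)), dim = ds) * sp^2
  dist_out_mm2 <- array(Inf, dim = d)
  dist_out_mm2[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub_d2
  dist_out_mm2[m > 0] <- 0
  dil <- m > 0 | dist_out_mm2 <= ext_mm^2
  # boundary truncation check: dilation touching the outermost voxel layer
  edge <- dil
  edge[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
  if (any(edge)) {
    rc_log("extend_rim: dilation truncated at the grid boundary")
    warning("rim extension truncated at grid boundary", call. = FALSE)
  }
  ext <- dil & !(as_plain(core) > 0)
  roi_mask(array(as.integer(ext), dim = d), sp, attr(entire, "origin_mm"),
    role = sprintf(
      "rim(%s)+ext(%g)", attr(core, "margin_mm") %||% "?", ext_mm
    )
  )
}

#' Restrict an ROI to a Hounsfield window (re-segmentation)
#'
#' Keeps mask voxels whose base-image intensity lies in `[lo, hi]`
#' (inclusive). Applied after sub-volume construction and before feature
#' extraction to drop air and bone voxels.
#'
#' @param image base [image_volume()] (HU).
#' @param mask [roi_mask()] to restrict.
#' @param lo,hi window bounds in HU.
#' @return The re-segmented [roi_mask()].
#' @export
resegment <- function(image, mask, lo = -150, hi = 180) {
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  assert_aligned(image, mask)
  idx <- which(as_plain(mask) > 0)
  v <- as_plain(image)[idx]
  idx <- idx[v >= lo & v <= hi]
  if (length(idx) == 0) stop("re-segmented ROI is empty", call. = FALSE)
  keep <- array(0L, dim = dim(mask))
  keep[idx] <- 1L
  out <- roi_mask(keep,
    spacing(mask)[1], attr(mask, "origin_mm"),
    role = attr(mask, "role")
  )
  attr(out, "resegmented") <- c(lo = lo, hi = hi)
  out
}

#' Mask volume in cubic centimetres
#'
#' @param mask an [roi_mask()].
#' @return Voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(as_plain(mask)) * prod(spacing(mask)) / 1000
}

#' Build the full sub-volume set for one margin
#'
#' Splits `entire` into rim and core at `margin_mm` (with the minimum-core
#' floor) and optionally adds extended rims.
#'
#' @param entire entire-tumour [roi_mask()] on an isotropic grid.
#' @param margin_mm inward margin (mm).
#' @param ext_mm numeric vector of outward extensions (mm), possibly empty.
#' @param min_fraction minimum core fraction.
#' @return A list: `entire`, `rim`, `core`, `extended` (named list by
#'   extension), `core_fraction`.
#' @export
subvolume_set <- function(entire, margin_mm, ext_mm = numeric(),
                          min_fraction = 0.40) {
  core <- make_core(entire, margin_mm, min_fraction)
  rim <- make_rim(entire, core)
  extended <- lapply(ext_mm, function(e) extend_rim(entire, core, e))
  names(extended) <- if (length(ext_mm)) sprintf("ext%g", ext_mm) else NULL
  list(
    entire = entire, rim = rim, core = core, extended = extended,
    core_fraction = attr(core, "core_fraction")
  )
}
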