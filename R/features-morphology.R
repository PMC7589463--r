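# Morphological (shape) features on the geometric mask. Mesh quantities come
# from a marching-tetrahedra iso-surface at 0.5; bounding/enclosing bodies
# from the voxel-centre point cloud (convex hull, PCA box, Khachiyan MVEE).

# voxel-centre coordinates (mm) of mask voxels, n x 3
mask_coords <- function(mask) {
  d <- dim(mask)
  sp <- spacing(mask)
  idx <- which(as_plain(mask) > 0)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  cbind(i * sp[1], j * sp[2], k * sp[3])
}

# extreme voxel centres per grid column along each axis: a small superset of
# the convex hull vertices of the voxel-centre cloud
extreme_points <- function(mask) {
  d <- dim(mask)
  m <- as_plain(mask) > 0
  pts <- list()
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    mp <- aperm(m, perm)
    dm <- dim(mp)
    flat <- matrix(mp, nrow = dm[1])
    has <- colSums(flat) > 0
    cols <- which(has)
    lo <- apply(flat[, cols, drop = FALSE], 2, function(v) which(v)[1])
    hi_ <- apply(flat[, cols, drop = FALSE], 2, function(v) {
      w <- which(v)
      w[length(w)]
    })
    b <- (cols - 1) %% dm[2]
    c_ <- (cols - 1) %/% dm[2]
    for (ax_val in list(lo, hi_)) {
      coord <- matrix(0, length(cols), 3)
      coord[, perm[1]] <- ax_val - 1
      coord[, perm[2]] <- b
      coord[, perm[3]] <- c_
      pts[[length(pts) + 1]] <- coord
    }
  }
  unique(do.call(rbind, pts))
}

# convex hull of the mask surface: hull of voxel-centre extremes, expanded by
# half-voxel face offsets to approximate the iso-surface extent
mask_hull <- function(mask) {
  sp <- spacing(mask)[1]
  cand <- extreme_points(mask)
  h1 <- .cpp_hull3d(cand + 0.0)
  if (length(h1$vertices) == 0) {
    return(NULL)
  }
  verts <- cand[h1$vertices, , drop = FALSE]
  offs <- rbind(
    c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0), c(0, -0.5, 0),
    c(0, 0, 0.5), c(0, 0, -0.5)
  )
  expanded <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r) {
    sweep(verts, 2, offs[r, ], `+`)
  }))
  h2 <- .cpp_hull3d(expanded)
  if (length(h2$vertices) == 0) {
    return(NULL)
  }
  list(
    volume = h2$volume * sp^3,
    area = h2$area * sp^2,
    vertices = expanded[h2$vertices, , drop = FALSE] * sp
  )
}

# minimum-volume enclosing ellipsoid (Khachiyan); returns semi-axes
mvee_semiaxes <- function(pts, tol = 1e-3, max_iter = 200) {
  n <- nrow(pts)
  if (n < 4) {
    return(NULL)
  }
  q <- t(cbind(pts, 1))
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x <- q %*% (u * t(q))
    xi <- tryCatch(solve(x), error = function(e) NULL)
    if (is.null(xi)) {
      return(NULL)
    }
    m <- colSums(q * (xi %*% q))
    jmax <- which.max(m)
    step <- (m[jmax] - 4) / (4 * (m[jmax] - 1))
    if (!is.finite(step) || step <= 0) break
    u_new <- (1 - step) * u
    u_new[jmax] <- u_new[jmax] + step
    if (sqrt(sum((u_new - u)^2)) < tol) {
      u <- u_new
      break
    }
    u <- u_new
  }
  ctr <- colSums(pts * u)
  a_mat <- tryCatch(
    solve(crossprod(pts * sqrt(u)) - tcrossprod(ctr)) / 3,
    error = function(e) NULL
  )
  if (is.null(a_mat)) {
    return(NULL)
  }
  ev <- eigen(a_mat, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    return(NULL)
  }
  sort(1 / sqrt(ev), decreasing = TRUE)
}

# Thomsen approximation to the ellipsoid surface area
ellipsoid_area <- function(ax) {
  p <- 1.6075
  4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p + ax[2]^p * ax[3]^p) / 3)^(1 / p)
}

morph_names <- function() {
  paste0("morph_", c(
    "vol_voxel", "vol_mesh", "area_mesh", "svr", "comp1", "comp2",
    "sph_dispr", "sphericity", "asphericity", "com_shift", "diam",
    "pca_major", "pca_minor", "pca_least", "elongation", "flatness",
    "vdens_aabb", "adens_aabb", "vdens_ombb", "adens_ombb",
    "vdens_aee", "adens_aee", "vdens_mvee",
    "vdens_ch", "adens_ch",
    "integ_int", "moran_i", "geary_c"
  ))
}

#' Morphological features (28)
#'
#' Shape descriptors of the geometric (non-re-segmented) mask: voxel and
#' surface-mesh volume, mesh surface area, surface-to-volume ratio, the
#' compactness/sphericity group, centre-of-mass shift, maximum 3D diameter,
#' PCA axis lengths with elongation and flatness, volume/area densities of
#' the axis-aligned and PCA-oriented bounding boxes, of the approximate
#' enclosing ellipsoid, of the minimum-volume enclosing ellipsoid (volume
#' density only) and of the convex hull, plus the intensity-weighted trio
#' (integrated intensity, Moran's I, Geary's C) computed on the supplied
#' intensity image restricted to `intensity_mask` (the re-segmented ROI).
#'
#' Masks with fewer than 4 non-coplanar voxels fall back from mesh/hull to
#' voxel-based values (logged). Spatial autocorrelation uses a deterministic
#' even-stride subsample above 1000 voxels.
#'
#' @param mask geometric [roi_mask()].
#' @param image optional base [image_volume()] for the intensity-weighted
#'   features.
#' @param intensity_mask optional re-segmented [roi_mask()]; defaults to
#'   `mask`.
#' @return Named numeric vector of length 28.
#' @export
morphology_features <- function(mask, image = NULL, intensity_mask = NULL) {
  n <- sum(as_plain(mask))
  if (n == 0) stop("empty mask", call. = FALSE)
  sp <- spacing(mask)[1]
  v_vox <- n * sp^3
  # marching-tetrahedra surface of the binary mask; a few Laplacian mesh
  # smoothing passes remove the half-voxel staircase that otherwise inflates
  # the area of oblique surfaces (costs a little accuracy at sharp edges)
  mesh <- .cpp_mesh(
    as.numeric(as_plain(mask)) + 0, as.integer(dim(mask)), 0.5, 5L, 0.5, 0
  )
  v_mesh <- mesh[1] * sp^3
  a_mesh <- mesh[2] * sp^2
  if (v_mesh <= 0) {
    rc_log("morphology: degenerate mesh, falling back to voxel volume")
    v_mesh <- v_vox
    a_mesh <- 6 * n * sp^2
  }
  coords <- mask_coords(mask)
  ctr <- colMeans(coords)

  sph <- (36 * pi * v_mesh^2)^(1 / 3) / a_mesh
  cov_m <- stats::cov(coords) * (n - 1) / max(n, 2) # population covariance
  if (n == 1) cov_m <- matrix(0, 3, 3)
  ev <- sort(pmax(eigen(cov_m, symmetric = TRUE)$values, 0),
    decreasing = TRUE
  )
  evec <- eigen(cov_m, symmetric = TRUE)$vectors
  axes_pca <- 4 * sqrt(ev)

  hull <- if (n >= 4) mask_hull(mask) else NULL
  if (is.null(hull)) {
    if (n >= 4) rc_log("morphology: degenerate hull, voxel fallback")
    hull <- list(volume = v_mesh, area = a_mesh, vertices = coords)
  }
  diam <- if (nrow(hull$vertices) >= 2) {
    sqrt(max(stats::dist(hull$vertices)^2))
  } else {
    0
  }

  aabb_ext <- mesh[3:5] * sp
  if (any(aabb_ext <= 0)) {
    rng <- apply(coords, 2, range)
    aabb_ext <- rng[2, ] - rng[1, ] + sp
  }
  proj <- coords %*% evec
  ombb_ext <- apply(proj, 2, function(v) diff(range(v))) + sp
  aee <- 2 * sqrt(ev)
  v_aee <- 4 / 3 * pi * prod(aee)
  mvee <- mvee_semiaxes(unique(hull$vertices))
  v_mvee <- if (is.null(mvee)) NA_real_ else 4 / 3 * pi * prod(mvee)
  if (is.null(mvee)) {
    rc_log("morphology: MVEE failed, volume density set to AEE value")
    v_mvee <- v_aee
  }

  # intensity-weighted trio
  integ <- moran <- geary <- 0
  com <- 0
  if (!is.null(image)) {
    imask <- intensity_mask %||% mask
    vals <- as_plain(image)[as_plain(imask) > 0]
    icoords <- mask_coords(imask)
    if (length(vals) > 1) {
      integ <- mean(vals) * v_mesh
      wctr <- colSums(icoords * vals) / sum(vals)
      com <- sqrt(sum((ctr - wctr)^2))
      sub <- if (length(vals) > 1000) {
        # deterministic even stride, no RNG
        round(seq(1, length(vals), length.out = 1000))
      } else {
        seq_along(vals)
      }
      xs <- vals[sub]
      cs <- icoords[sub, , drop = FALSE]
      dd <- as.matrix(stats::dist(cs))
      w <- ifelse(dd > 0, 1 / dd, 0)
      sw <- sum(w)
      mu <- mean(xs)
      dev <- xs - mu
      denom <- sum(dev^2)
      if (denom > 0 && sw > 0) {
        moran <- (length(xs) / sw) * sum(w * outer(dev, dev)) / denom
        geary <- ((length(xs) - 1) / (2 * sw)) *
          sum(w * outer(xs, xs, `-`)^2) / denom
      } else {
        rc_log("morphology: constant intensities, Moran/Geary set to 0")
      }
    }
  }

  vals <- c(
    v_vox, v_mesh, a_mesh, a_mesh / v_mesh,
    v_mesh / (sqrt(pi) * a_mesh^1.5),
    36 * pi * v_mesh^2 / a_mesh^3,
    1 / sph, sph, 1 / sph - 1,
    com, diam,
    axes_pca[1], axes_pca[2], axes_pca[3],
    if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1,
    v_mesh / prod(aabb_ext), a_mesh /
      (2 * (aabb_ext[1] * aabb_ext[2] + aabb_ext[1] * aabb_ext[3] +
        aabb_ext[2] * aabb_ext[3])),
    v_mesh / prod(ombb_ext), a_mesh /
      (2 * (ombb_ext[1] * ombb_ext[2] + ombb_ext[1] * ombb_ext[3] +
        ombb_ext[2] * ombb_ext[3])),
    if (v_aee > 0) v_mesh / v_aee else 0,
    if (v_aee > 0) a_mesh / ellipsoid_area(aee) else 0,
    if (v_mvee > 0) v_mesh / v_mvee else 0,
    v_mesh / hull$volume, a_mesh / hull$area,
    integ, moran, geary
  )
  stats::setNames(vals, morph_names())
}
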