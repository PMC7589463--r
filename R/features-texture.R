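# IBSI texture families computed from grey-level matrices. Co-occurrence and
# run-length matrices are built per 13 unique 3D directions (Chebyshev
# distance 1) and their features averaged over directions; zone, distance and
# dependence families use 26-connected neighbourhoods.

glcm_features_one <- function(counts) {
  ng <- nrow(counts)
  s <- sum(counts)
  if (s == 0) {
    return(stats::setNames(rep(0, 25), glcm_names()))
  }
  p <- counts / s
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mu <- sum(i * p)
  sx <- sqrt(sum((seq_len(ng) - mu)^2 * px))
  pd <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ps <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum((0:(ng - 1)) * pd)
  sa <- sum((2:(2 * ng)) * ps)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  hxy <- ent(p)
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)
  hx <- ent(px)
  corr <- if (sx > 0) (sum(i * j * p) - mu^2) / sx^2 else 0
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  off <- i - j
  vals <- c(
    joint_max = max(p),
    joint_avg = mu,
    joint_var = sum((i - mu)^2 * p),
    joint_entropy = hxy,
    diff_avg = da,
    diff_var = sum(((0:(ng - 1)) - da)^2 * pd),
    diff_entropy = ent(pd),
    sum_avg = sa,
    sum_var = sum(((2:(2 * ng)) - sa)^2 * ps),
    sum_entropy = ent(ps),
    energy = sum(p^2),
    contrast = sum(off^2 * p),
    dissimilarity = sum(abs(off) * p),
    inv_diff = sum(p / (1 + abs(off))),
    inv_diff_norm = sum(p / (1 + abs(off) / ng)),
    inv_diff_mom = sum(p / (1 + off^2)),
    inv_diff_mom_norm = sum(p / (1 + off^2 / ng^2)),
    inv_var = sum(p[off != 0] / off[off != 0]^2),
    correlation = corr,
    autocorr = sum(i * j * p),
    clust_tend = sum((i + j - 2 * mu)^2 * p),
    clust_shade = sum((i + j - 2 * mu)^3 * p),
    clust_prom = sum((i + j - 2 * mu)^4 * p),
    info_corr1 = ic1,
    info_corr2 = ic2
  )
  stats::setNames(vals, glcm_names())
}

glcm_names <- function() {
  c(
    "joint_max", "joint_avg", "joint_var", "joint_entropy", "diff_avg",
    "diff_var", "diff_entropy", "sum_avg", "sum_var", "sum_entropy",
    "energy", "contrast", "dissimilarity", "inv_diff", "inv_diff_norm",
    "inv_diff_mom", "inv_diff_mom_norm", "inv_var", "correlation",
    "autocorr", "clust_tend", "clust_shade", "clust_prom", "info_corr1",
    "info_corr2"
  )
}

# shared structure of the run/zone/distance families: matrix m indexed by
# grey level (rows) and a size-like variable j (columns)
rl_family <- function(m, n_vox, prefix, jname) {
  ns <- sum(m)
  ng <- nrow(m)
  nj <- ncol(m)
  nm <- c(
    "sje", "lje", "lgle", "hgle", "sjlgle", "sjhgle", "ljlgle", "ljhgle",
    "glnu", "glnun", "jnu", "jnun", "pct", "glv", "jv", "jentropy"
  )
  nm <- sub("j", jname, nm, fixed = TRUE)
  nm <- paste0(prefix, "_", nm)
  if (ns == 0) {
    return(stats::setNames(rep(0, 16), nm))
  }
  i <- matrix(seq_len(ng), ng, nj)
  j <- matrix(seq_len(nj), ng, nj, byrow = TRUE)
  p <- m / ns
  ri <- rowSums(m)
  rj <- colSums(m)
  mui <- sum(i * p)
  muj <- sum(j * p)
  pos <- p[p > 0]
  vals <- c(
    sum(m / j^2) / ns,
    sum(m * j^2) / ns,
    sum(m / i^2) / ns,
    sum(m * i^2) / ns,
    sum(m / (i^2 * j^2)) / ns,
    sum(m * i^2 / j^2) / ns,
    sum(m * j^2 / i^2) / ns,
    sum(m * i^2 * j^2) / ns,
    sum(ri^2) / ns,
    sum(ri^2) / ns^2,
    sum(rj^2) / ns,
    sum(rj^2) / ns^2,
    ns / n_vox,
    sum((i - mui)^2 * p),
    sum((j - muj)^2 * p),
    -sum(pos * log2(pos))
  )
  stats::setNames(vals, nm)
}

ngtdm_features <- function(acc, n_vox) {
  n_i <- acc[, 1]
  s_i <- acc[, 2]
  ng <- nrow(acc)
  n <- sum(n_i)
  nm <- c(
    "ngt_coarseness", "ngt_contrast", "ngt_busyness", "ngt_complexity",
    "ngt_strength"
  )
  if (n == 0) {
    return(stats::setNames(rep(0, 5), nm))
  }
  p_i <- n_i / n
  pres <- which(p_i > 0)
  ngp <- length(pres)
  den <- sum(p_i * s_i)
  coarse <- if (den > 0) min(1 / den, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    pij <- outer(p_i[pres], p_i[pres])
    dij <- outer(pres, pres, `-`)
    sum(pij * dij^2) / (ngp * (ngp - 1)) * sum(s_i) / n
  } else {
    0
  }
  busy_den <- sum(abs(outer(pres * p_i[pres], pres * p_i[pres], `-`)))
  busy <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  comp <- 0
  strength_num <- 0
  for (a in pres) {
    for (b in pres) {
      if (a == b) next
      comp <- comp +
        abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
      strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
    }
  }
  comp <- comp / n
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  stats::setNames(c(coarse, contrast, busy, comp, strength), nm)
}

ngldm_features <- function(counts, n_vox) {
  # counts: Ng x 27 with dependence count k in 0..26; features use j = k + 1
  base <- rl_family(counts, n_vox, "ngl", "dc")
  names(base) <- paste0("ngl_", c(
    "lde", "hde", "lgle", "hgle", "ldlgle", "ldhgle", "hdlgle", "hdhgle",
    "glnu", "glnun", "dcnu", "dcnun", "dcp", "glv", "dcv", "dcentropy"
  ))
  p <- if (sum(counts) > 0) counts / sum(counts) else counts
  c(base, ngl_dcenergy = sum(p^2))
}

#' Texture features (95) from a discretised ROI
#'
#' Grey-level co-occurrence (25), run length (16), size zone (16), distance
#' zone (16), neighbourhood grey-tone difference (5) and neighbouring
#' grey-level dependence (17) features. GLCM and GLRLM are accumulated per 13
#' unique 3D directions at distance 1 (GLCM symmetrised) and their features
#' averaged over directions; zone families use 26-connected zones, and the
#' distance-zone map uses the city-block distance to the ROI border. A
#' single-voxel ROI yields the defined degenerate values (logged).
#'
#' @param levels 3D integer array of grey levels, `1..n_levels` inside the
#'   ROI and `0` outside.
#' @param n_levels number of grey levels used in the discretisation.
#' @return Named numeric vector of length 95.
#' @export
texture_features <- function(levels, n_levels) {
  stopifnot(is.array(levels), length(dim(levels)) == 3L)
  d <- dim(levels)
  lv <- as.integer(levels)
  n_vox <- sum(lv > 0)
  if (n_vox < 2) rc_log("texture_features: ROI has <2 voxels, degenerate")
  ng <- as.integer(n_levels)

  glcm <- .cpp_glcm(lv, as.integer(d), ng)
  glcm_per_dir <- apply(glcm, 3, function(m) glcm_features_one(matrix(m, ng, ng)))
  glcm_avg <- rowMeans(glcm_per_dir)
  names(glcm_avg) <- paste0("glcm_", glcm_names())

  glrlm <- .cpp_glrlm(lv, as.integer(d), ng)
  lmax <- dim(glrlm)[2]
  glrlm_per_dir <- apply(glrlm, 3, function(m) {
    rl_family(matrix(m, ng, lmax), n_vox, "glrlm", "r")
  })
  glrlm_avg <- rowMeans(glrlm_per_dir)

  dist_map <- .cpp_manhattan_dist(as.integer(lv > 0), as.integer(d))
  zones <- .cpp_zones(lv, as.integer(d), dist_map)
  smax <- max(zones[, 2], 1L)
  dmax <- max(zones[, 3], 1L)
  szm <- matrix(0, ng, smax)
  dzm <- matrix(0, ng, dmax)
  for (r in seq_len(nrow(zones))) {
    szm[zones[r, 1], zones[r, 2]] <- szm[zones[r, 1], zones[r, 2]] + 1
    dzm[zones[r, 1], zones[r, 3]] <- dzm[zones[r, 1], zones[r, 3]] + 1
  }
  glszm <- rl_family(szm, n_vox, "glszm", "z")
  gldzm <- rl_family(dzm, n_vox, "gldzm", "zd")

  ngt <- ngtdm_features(.cpp_ngtdm(lv, as.integer(d), ng), n_vox)
  ngl <- ngldm_features(.cpp_ngldm(lv, as.integer(d), ng, 0L), n_vox)

  c(glcm_avg, glrlm_avg, glszm, gldzm, ngt, ngl)
}
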