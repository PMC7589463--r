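# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (full enumeration) so they cannot share defects with
# the implementation paths they check.

sphere_mask <- function(radius_mm, spacing = 1, margin = 5) {
  n <- 2 * ceiling(radius_mm / spacing) + 2 * margin + 1
  c0 <- (n - 1) / 2 * spacing
  x <- (seq_len(n) - 1) * spacing - c0
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  roi_mask(array(as.integer(r2 <= radius_mm^2), dim = c(n, n, n)), spacing)
}

# all-pairs Euclidean distance of each mask voxel to the nearest background
# voxel centre (the stated oracle for the distance-transform path)
brute_dist_to_background <- function(mask) {
  d <- dim(mask)
  coords <- as.matrix(expand.grid(
    i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3])
  ))
  m <- as.vector(mask) > 0
  fg <- coords[m, , drop = FALSE]
  bg <- coords[!m, , drop = FALSE]
  out <- numeric(sum(m))
  for (r in seq_len(nrow(fg))) {
    dd <- sweep(bg, 2, fg[r, ])
    out[r] <- sqrt(min(rowSums(dd^2)))
  }
  res <- array(0, dim = d)
  res[m] <- out
  res
}

# the 13 unique 3D directions used for GLCM/GLRLM aggregation
DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

brute_glcm <- function(levels, ng, dir) {
  d <- dim(levels)
  m <- matrix(0, ng, ng)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        a <- levels[i, j, k]
        if (a == 0) next
        p <- c(i, j, k) + dir
        if (any(p < 1) || any(p > d)) next
        b <- levels[p[1], p[2], p[3]]
        if (b == 0) next
        m[a, b] <- m[a, b] + 1
        m[b, a] <- m[b, a] + 1
      }
    }
  }
  m
}

brute_glrlm <- function(levels, ng, dir) {
  d <- dim(levels)
  counts <- matrix(0, ng, max(d))
  seen_start <- function(p) {
    q <- p - dir
    if (any(q < 1) || any(q > d)) {
      return(TRUE)
    }
    levels[q[1], q[2], q[3]] != levels[p[1], p[2], p[3]]
  }
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        p <- c(i, j, k)
        a <- levels[i, j, k]
        if (a == 0 || !seen_start(p)) next
        len <- 1
        q <- p + dir
        while (all(q >= 1) && all(q <= d) && levels[q[1], q[2], q[3]] == a) {
          len <- len + 1
          q <- q + dir
        }
        counts[a, len] <- counts[a, len] + 1
      }
    }
  }
  counts
}

# 26-connected zones by repeated flood fill
brute_zones <- function(levels) {
  d <- dim(levels)
  lab <- array(0L, dim = d)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (start in which(levels > 0 & lab == 0)) {
    if (lab[start] != 0) next
    lev <- levels[start]
    stack <- start
    members <- integer(0)
    lab[start] <- 1L
    while (length(stack)) {
      t <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, t)
      k <- (t - 1) %/% (d[1] * d[2]) + 1
      j <- ((t - 1) %/% d[1]) %% d[2] + 1
      i <- (t - 1) %% d[1] + 1
      for (r in seq_len(nrow(nb))) {
        p <- c(i, j, k) + nb[r, ]
        if (any(p < 1) || any(p > d)) next
        t2 <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (lab[t2] == 0 && levels[t2] == lev) {
          lab[t2] <- 1L
          stack <- c(stack, t2)
        }
      }
    }
    zones[[length(zones) + 1]] <- list(level = lev, size = length(members))
  }
  zones
}

# Harrell's C with half credit for risk ties; pairs comparable when the
# shorter time is an event (ties in time: event precedes censoring)
brute_cindex <- function(risk, time, event) {
  conc <- 0
  np <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1) next # both events / both censored
        ev <- if (event[i] == 1) i else j
        np <- np + 1
        conc <- conc + if (risk[ev] > risk[c(i, j)[c(i, j) != ev]]) {
          1
        } else if (risk[ev] < risk[c(i, j)[c(i, j) != ev]]) 0 else 0.5
      } else {
        first <- if (time[i] < time[j]) i else j
        second <- c(i, j)[c(i, j) != first]
        if (event[first] != 1) next
        np <- np + 1
        conc <- conc + if (risk[first] > risk[second]) {
          1
        } else if (risk[first] < risk[second]) 0 else 0.5
      }
    }
  }
  conc / np
}

# small feature table with one signal feature and pure-noise companions
toy_features <- function(n = 100, n_noise = 8, beta = 2, seed = 5) {
  withr::with_seed(seed, {
    z <- stats::rnorm(n)
    tab <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      f_signal = z + stats::rnorm(n, 0, 0.3)
    )
    for (j in seq_len(n_noise)) {
      tab[[sprintf("f_noise%02d", j)]] <- stats::rnorm(n)
    }
    list(
      features = tab,
      outcomes = generate_outcomes(z, outcome_spec(beta = beta, seed = seed)),
      z = z
    )
  })
}
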