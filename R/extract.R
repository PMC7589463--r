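TRANSFORM_LABELS <- c(
  "base",
  paste0("wav_", c("HHH", "HHL", "HLH", "HLL", "LHH", "LHL", "LLH", "LLL")),
  "log"
)

stat_names <- function() {
  c(
    "mean", "var", "skew", "kurt", "median", "min", "p10", "p90", "max",
    "iqr", "range", "mad", "madr", "medad", "cov", "qcod", "energy", "rms"
  )
}

hist_feat_names <- function() {
  c(
    paste0("ih_", c(
      "mean", "var", "skew", "kurt", "median", "min", "p10", "p90", "max",
      "iqr", "range", "mad", "madr", "medad", "cov", "qcod", "mode",
      "entropy", "uniformity", "max_grad", "max_grad_level", "min_grad",
      "min_grad_level"
    )),
    paste0("ivh_", c(
      "v10", "v25", "v50", "v75", "v90", "i10", "i25", "i50", "i75", "i90",
      "diff_v10_v90", "diff_i10_i90", "auc"
    )),
    "loc_peak_local", "loc_peak_global"
  )
}

texture_feat_names <- function() {
  c(
    paste0("glcm_", glcm_names()),
    paste0("glrlm_", c(
      "sre", "lre", "lgle", "hgle", "srlgle", "srhgle", "lrlgle", "lrhgle",
      "glnu", "glnun", "rnu", "rnun", "pct", "glv", "rv", "rentropy"
    )),
    paste0("glszm_", c(
      "sze", "lze", "lgle", "hgle", "szlgle", "szhgle", "lzlgle", "lzhgle",
      "glnu", "glnun", "znu", "znun", "pct", "glv", "zv", "zentropy"
    )),
    paste0("gldzm_", c(
      "szde", "lzde", "lgle", "hgle", "szdlgle", "szdhgle", "lzdlgle",
      "lzdhgle", "glnu", "glnun", "zdnu", "zdnun", "pct", "glv", "zdv",
      "zdentropy"
    )),
    c(
      "ngt_coarseness", "ngt_contrast", "ngt_busyness", "ngt_complexity",
      "ngt_strength"
    ),
    paste0("ngl_", c(
      "lde", "hde", "lgle", "hgle", "ldlgle", "ldhgle", "hdlgle", "hdhgle",
      "glnu", "glnun", "dcnu", "dcnun", "dcp", "glv", "dcv", "dcentropy",
      "dcenergy"
    ))
  )
}

#' The frozen feature manifest
#'
#' The ordered list of feature names with family and image-transform
#' provenance. Per ROI this expands to (18 statistical + 38 histogram + 95
#' texture) features on each of the 10 images plus 28 morphological features
#' on the base image: 1538 entries.
#'
#' @param transforms transform labels to include (default all 10).
#' @param families feature families to include.
#' @return A tibble with columns `name`, `family`, `transform`.
#' @export
feature_manifest <- function(transforms = TRANSFORM_LABELS,
                             families = c(
                               "statistical", "histogram", "texture",
                               "morphology"
                             )) {
  families <- match.arg(families, several.ok = TRUE)
  rows <- list()
  for (tr in transforms) {
    if ("statistical" %in% families) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = paste0(tr, "_stat_", stat_names()),
        family = "statistical", transform = tr
      )
    }
    if ("histogram" %in% families) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = paste0(tr, "_", hist_feat_names()),
        family = "histogram", transform = tr
      )
    }
    if ("texture" %in% families) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = paste0(tr, "_", texture_feat_names()),
        family = "texture", transform = tr
      )
    }
  }
  if ("morphology" %in% families && "base" %in% transforms) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = morph_names(), family = "morphology", transform = "base"
    )
  }
  dplyr::bind_rows(rows)
}

#' Extract the full feature vector for one ROI
#'
#' Re-segments the ROI on the base image (HU window), computes the 18+38+95
#' intensity/histogram/texture features on the base image and on each
#' transformed image of the filter bank, and the 28 morphology features on
#' the geometric mask. Filtered images are masked with the base-image
#' re-segmentation (HU thresholds are meaningless on filter responses).
#'
#' @param image base [image_volume()] on an isotropic grid.
#' @param mask geometric [roi_mask()] for the ROI.
#' @param bank optional precomputed [filter_bank()] result (to share across
#'   ROIs of one patient).
#' @param transforms transform labels to compute.
#' @param families feature families to compute.
#' @param n_bins grey levels for fixed-bin-number discretisation.
#' @param hu_window re-segmentation window on the base image.
#' @return Named numeric vector (1538 values at the defaults), or `NULL`
#'   with a log record when the re-segmented ROI is empty.
#' @export
extract_features <- function(image, mask, bank = NULL,
                             transforms = TRANSFORM_LABELS,
                             families = c(
                               "statistical", "histogram", "texture",
                               "morphology"
                             ),
                             n_bins = 32, hu_window = c(-150, 180)) {
  families <- match.arg(families, several.ok = TRUE)
  reseg <- tryCatch(
    resegment(image, mask, hu_window[1], hu_window[2]),
    error = function(e) NULL
  )
  if (is.null(reseg)) {
    rc_log("extract_features: empty re-segmented ROI ('%s'), row omitted",
      attr(mask, "role") %||% "?")
    return(NULL)
  }
  if (is.null(bank)) {
    needed <- setdiff(transforms, "base")
    bank <- if (length(needed)) filter_bank(image) else list(base = image)
  }
  sel <- as_plain(reseg) > 0
  d <- dim(image)
  out <- list()
  for (tr in transforms) {
    img_t <- bank[[tr]]
    vals <- as_plain(img_t)[sel]
    part <- c()
    if ("statistical" %in% families) {
      part <- c(part, statistical_features(vals))
    }
    if ("histogram" %in% families || "texture" %in% families) {
      droi <- discretise(vals, n_bins)
      if ("histogram" %in% families) {
        part <- c(part, histogram_features(droi, vals, img_t, reseg))
      }
      if ("texture" %in% families) {
        lev_arr <- array(0L, dim = d)
        lev_arr[sel] <- droi$levels
        part <- c(part, texture_features(lev_arr, droi$n_levels))
      }
    }
    names(part) <- paste0(tr, "_", names(part))
    out[[tr]] <- part
  }
  res <- unlist(out, use.names = TRUE)
  names(res) <- sub("^[^.]*\\.", "", names(res))
  if ("morphology" %in% families && "base" %in% transforms) {
    res <- c(res, morphology_features(mask, image, intensity_mask = reseg))
  }
  bad <- !is.finite(res)
  if (any(bad)) {
    rc_log(
      "extract_features: %d non-finite values imputed to 0 (%s)",
      sum(bad), paste(utils::head(names(res)[bad], 3), collapse = ", ")
    )
    res[bad] <- 0
  }
  res
}

#' Extract features for every sub-volume of one patient
#'
#' @param image base [image_volume()].
#' @param subvols named list of [roi_mask()]s (e.g. from [subvolume_set()],
#'   flattened), names used as ROI labels.
#' @param ... passed to [extract_features()].
#' @return A tibble with columns `roi` and one column per feature.
#' @export
extract_all <- function(image, subvols, ...) {
  rows <- purrr::imap(subvols, function(m, nm) {
    v <- extract_features(image, m, ...)
    if (is.null(v)) {
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(roi = nm), tibble::as_tibble_row(v))
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Sub-volume labels for a margin/extension grid
#'
#' @param margins_mm inward margins.
#' @param extensions_mm outward extensions, applied to `ext_margin_mm`.
#' @param ext_margin_mm the rim margin that receives the extensions.
#' @return Character vector of ROI labels (`"entire"`, `"rim5"`, `"core5"`,
#'   `"rim5+ext3"`, ...).
#' @export
roi_labels <- function(margins_mm = c(3, 5), extensions_mm = c(1, 2, 3, 5),
                       ext_margin_mm = max(margins_mm)) {
  c(
    "entire",
    as.vector(rbind(
      sprintf("rim%g", margins_mm), sprintf("core%g", margins_mm)
    )),
    sprintf("rim%g+ext%g", ext_margin_mm, extensions_mm)
  )
}

#' Sub-volume feature table for a whole synthetic cohort
#'
#' Regenerates each patient's phantom once, builds every requested
#' sub-volume (sharing the filter bank across ROIs) and extracts features.
#' Patients whose re-segmented ROI is empty are omitted with a log record.
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param rois ROI labels as produced by [roi_labels()].
#' @param min_fraction minimum core fraction.
#' @param ... passed to [extract_features()] (e.g. `transforms`,
#'   `families`).
#' @return A tibble: `patient_id`, `roi`, features.
#' @export
cohort_features <- function(cohort, rois = c("rim5", "core5"),
                            min_fraction = 0.40, ...) {
  stopifnot(inherits(cohort, "rimcore_cohort"))
  needed <- setdiff(list(...)$transforms %||% TRANSFORM_LABELS, "base")
  margins <- unique(as.numeric(
    sub("^(rim|core)([0-9.]+).*$", "\\2", grep("^(rim|core)", rois, value = TRUE))
  ))
  res <- purrr::map(seq_len(nrow(cohort)), function(i) {
    ph <- cohort_phantom(cohort, i)
    masks <- list()
    if ("entire" %in% rois) masks$entire <- ph$mask
    for (m in margins) {
      exts <- grep(sprintf("^rim%g\\+ext", m), rois, value = TRUE)
      ext_mm <- as.numeric(sub(".*\\+ext([0-9.]+)$", "\\1", exts))
      sv <- subvolume_set(ph$mask, m,
        ext_mm = ext_mm,
        min_fraction = min_fraction
      )
      if (sprintf("rim%g", m) %in% rois) {
        masks[[sprintf("rim%g", m)]] <- sv$rim
      }
      if (sprintf("core%g", m) %in% rois) {
        masks[[sprintf("core%g", m)]] <- sv$core
      }
      for (e in seq_along(ext_mm)) {
        masks[[exts[e]]] <- sv$extended[[e]]
      }
    }
    bank <- if (length(needed)) filter_bank(ph$image) else list(base = ph$image)
    tab <- extract_all(ph$image, masks, bank = bank, ...)
    if (nrow(tab) == 0) {
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(patient_id = cohort$patient_id[i]),
      tab
    )
  })
  dplyr::bind_rows(purrr::compact(res))
}
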