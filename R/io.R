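#' Read a 3D NIfTI image or mask
#'
#' Voxel spacing is taken from the header. Masks are validated as binary;
#' the common `{0, 255}` dialect is normalised to `{0, 1}` with a log
#' record.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param as_mask read as an [roi_mask()] instead of an [image_volume()].
#' @param role mask role label.
#' @return An [image_volume()] or [roi_mask()].
#' @export
read_nifti <- function(path, as_mask = FALSE, role = "entire") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(arr)), "D", call. = FALSE)
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop("missing or invalid voxel spacing in header", call. = FALSE)
  }
  if (!as_mask) {
    return(image_volume(arr, sp[1:3]))
  }
  vals <- sort(unique(as.vector(arr)))
  if (identical(vals, c(0, 255)) || identical(vals, 255)) {
    rc_log("read_nifti: mask values {0, 255} normalised to {0, 1}")
    arr <- arr / 255
  } else if (!all(vals %in% c(0, 1))) {
    stop("mask is not binary", call. = FALSE)
  }
  roi_mask(arr, sp[1:3], role = role)
}

#' Write an image or mask as NIfTI
#'
#' @param x [image_volume()] or [roi_mask()].
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  arr <- as_plain(x) + 0
  nii <- RNifti::asNifti(arr, pixdim = spacing(x))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Materialise a synthetic cohort on disk
#'
#' Writes one image and mask NIfTI pair per patient plus a cohort manifest
#' CSV (`patient_id`, `cohort`, `time_months`, `event`, `volume_cm3`) with
#' a provenance header.
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rimcore_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    ph <- cohort_phantom(cohort, i)
    write_nifti(ph$image, file.path(
      dir, sprintf("%s_image.nii.gz", cohort$patient_id[i])
    ))
    write_nifti(ph$mask, file.path(
      dir, sprintf("%s_mask.nii.gz", cohort$patient_id[i])
    ))
  }
  manifest <- file.path(dir, "cohort.csv")
  write_csv_provenance(
    cohort[, c("patient_id", "cohort", "time_months", "event", "volume_cm3")],
    manifest,
    seed = attr(cohort, "phantom_spec")$seed
  )
  invisible(manifest)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable FNV-1a style hash, no external deps
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_csv_provenance <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# rimcore output | config %s | seed %s",
    if (is.null(config)) "-" else config_hash(config),
    if (is.null(seed)) "-" else seed
  ), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_provenance <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
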