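#' Construct a patient volume
#'
#' Bundles co-registered PET (SUV-valued), CT and binary lesion mask grids
#' with their common voxel spacing. All three grids must share shape and
#' spacing; SUV values must be non-negative.
#'
#' @param pet,ct 3D numeric arrays.
#' @param mask 3D array, binarized at 0.5.
#' @param spacing Voxel spacing in mm per axis (length 3).
#' @param patient_id Identifier.
#' @return A `patient_volume` object.
#' @export
patient_volume <- function(pet, ct, mask, spacing, patient_id = "p") {
  if (!identical(dim(pet), dim(ct)))
    stop("shape mismatch between PET (", paste(dim(pet), collapse = "x"),
         ") and CT (", paste(dim(ct), collapse = "x"), ")")
  if (!identical(dim(pet), dim(mask)))
    stop("shape mismatch between PET (", paste(dim(pet), collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"), ")")
  stopifnot(length(dim(pet)) == 3, length(spacing) == 3, all(spacing > 0))
  if (min(pet) < -1e-6) stop("PET volume contains negative SUV values")
  pet[pet < 0] <- 0
  mask <- array(as.integer(mask > 0.5), dim(mask))
  structure(list(pet = pet, ct = ct, mask = mask,
                 spacing = as.numeric(spacing), patient_id = patient_id),
            class = "patient_volume")
}

#' @export
print.patient_volume <- function(x, ...) {
  cat("PET/CT patient volume", x$patient_id, "\n")
  cat("  grid:", paste(dim(x$pet), collapse = " x "), "voxels @",
      paste(round(x$spacing, 2), collapse = " x "), "mm\n")
  cat("  lesion voxels:", sum(x$mask), "\n")
  invisible(x)
}

#' Write / read a patient volume as NIfTI
#'
#' `write_patient()` writes the PET, CT and mask grids as NIfTI files with
#' the voxel spacing in the header; `read_patient()` reads them back,
#' checks that the three grids agree in shape and spacing, and binarizes
#' the mask at 0.5.
#'
#' @param volume A [patient_volume()].
#' @param paths Named list/vector with elements `pet`, `ct`, `mask`.
#' @param patient_id Identifier for the reconstructed volume.
#' @return `read_patient()` returns a [patient_volume()].
#' @export
write_patient <- function(volume, paths) {
  stopifnot(inherits(volume, "patient_volume"))
  for (ch in c("pet", "ct", "mask")) {
    img <- RNifti::asNifti(volume[[ch]])
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, paths[[ch]])
  }
  invisible(paths)
}

#' @rdname write_patient
#' @export
read_patient <- function(paths, patient_id = "p") {
  imgs <- lapply(paths[c("pet", "ct", "mask")], RNifti::readNifti)
  dims <- lapply(imgs, dim)
  sps <- lapply(imgs, function(i) RNifti::pixdim(i)[1:3])
  for (ch in c("ct", "mask")) {
    if (!identical(dims$pet, dims[[ch]]))
      stop("shape mismatch between PET (", paste(dims$pet, collapse = "x"),
           ") and ", ch, " (", paste(dims[[ch]], collapse = "x"), ")")
    if (max(abs(sps$pet - sps[[ch]])) > 1e-4)
      stop("voxel spacing mismatch between PET and ", ch)
  }
  strip <- function(img) array(as.numeric(img), dim(img))
  patient_volume(pet = strip(imgs$pet), ct = strip(imgs$ct),
                 mask = strip(imgs$mask), spacing = as.numeric(sps$pet),
                 patient_id = patient_id)
}

#' Crop and resample a lesion region of interest
#'
#' Extracts a physical cube of side `side_mm` centred on the lesion mask
#' centroid and trilinearly resamples it to `out_voxels` per axis, giving a
#' two-channel (PET, CT) network input tensor. The PET channel stays in SUV
#' units unless normalization statistics are supplied, in which case it is
#' z-scored with them; the CT channel is min-max scaled to [0, 1]. Sample
#' points falling outside the source grid take the per-channel background
#' value (0 after normalization).
#'
#' @param volume A [patient_volume()] with a non-empty mask.
#' @param side_mm Physical side length of the cropped cube (mm).
#' @param out_voxels Output voxels per axis.
#' @param norm_stats Optional list with `pet_mean`, `pet_sd`, `ct_min`,
#'   `ct_max` (typically training-cohort statistics from
#'   [roi_norm_stats()]); `NULL` leaves channels on their native scales.
#' @param pet_only Emit a single-channel (PET) tensor.
#' @return A `roi_tensor`: list with `data` (array `(channels, n, n, n)`),
#'   `source_bbox` (index ranges of the sampled window in the source
#'   grid), `in_grid` (logical array marking samples inside the source
#'   grid) and `normalization` (parameters actually applied).
#' @export
crop_resample <- function(volume, side_mm = 96, out_voxels = 32,
                          norm_stats = NULL, pet_only = FALSE) {
  stopifnot(inherits(volume, "patient_volume"))
  if (sum(volume$mask) == 0) stop("empty lesion mask: nothing to crop")
  dm <- dim(volume$pet)
  idx <- which(volume$mask > 0, arr.ind = TRUE) - 1  # 0-based voxel coords
  centroid <- colMeans(idx)
  n <- out_voxels
  step_mm <- side_mm / n
  off <- (seq_len(n) - 1 - (n - 1) / 2) * step_mm
  pts <- as.matrix(expand.grid(x = off, y = off, z = off))
  pts <- sweep(pts, 2, volume$spacing, "/")
  pts <- sweep(pts, 2, centroid, "+")

  pet <- .sample_trilinear(volume$pet, as.integer(dm), pts, NA_real_)
  ct <- .sample_trilinear(volume$ct, as.integer(dm), pts, NA_real_)
  in_grid <- !is.na(pet)

  if (is.null(norm_stats)) {
    pet[!in_grid] <- 0
    ct[!in_grid] <- 0
    applied <- list(pet_shift = 0, pet_scale = 1, ct_min = NA, ct_max = NA)
  } else {
    pet <- (pet - norm_stats$pet_mean) / norm_stats$pet_sd
    rng <- norm_stats$ct_max - norm_stats$ct_min
    ct <- (ct - norm_stats$ct_min) / if (rng > 0) rng else 1
    ct <- pmin(pmax(ct, 0), 1)
    pet[!in_grid] <- 0
    ct[!in_grid] <- 0
    applied <- list(pet_shift = norm_stats$pet_mean,
                    pet_scale = norm_stats$pet_sd,
                    ct_min = norm_stats$ct_min, ct_max = norm_stats$ct_max)
  }

  nc <- if (pet_only) 1L else 2L
  data <- array(0, c(nc, n, n, n))
  data[1, , , ] <- array(pet, c(n, n, n))
  if (!pet_only) data[2, , , ] <- array(ct, c(n, n, n))
  bbox <- rbind(lo = floor(apply(pts, 2, min)),
                hi = ceiling(apply(pts, 2, max)))
  structure(list(data = data,
                 source_bbox = bbox,
                 in_grid = array(in_grid, c(n, n, n)),
                 normalization = applied,
                 patient_id = volume$patient_id),
            class = "roi_tensor")
}

# Apply frozen cohort statistics to a raw ROI tensor; identical result to
# calling crop_resample() with norm_stats directly.
normalize_roi <- function(roi, norm_stats) {
  stopifnot(inherits(roi, "roi_tensor"))
  pet <- (roi$data[1, , , ] - norm_stats$pet_mean) / norm_stats$pet_sd
  pet[!roi$in_grid] <- 0
  roi$data[1, , , ] <- pet
  if (dim(roi$data)[1] > 1) {
    rng <- norm_stats$ct_max - norm_stats$ct_min
    ct <- (roi$data[2, , , ] - norm_stats$ct_min) / if (rng > 0) rng else 1
    ct <- pmin(pmax(ct, 0), 1)
    ct[!roi$in_grid] <- 0
    roi$data[2, , , ] <- ct
  }
  roi$normalization <- list(pet_shift = norm_stats$pet_mean,
                            pet_scale = norm_stats$pet_sd,
                            ct_min = norm_stats$ct_min,
                            ct_max = norm_stats$ct_max)
  roi
}

#' Cohort normalization statistics for ROI tensors
#'
#' Computes the PET mean/SD and CT range over the in-grid voxels of a set
#' of raw (unnormalized) ROI tensors. Computed on the training cohort once
#' and then frozen for test-time use, so no test-set information leaks into
#' the normalization.
#'
#' @param rois List of raw `roi_tensor`s from [crop_resample()].
#' @return List with `pet_mean`, `pet_sd`, `ct_min`, `ct_max`.
#' @export
roi_norm_stats <- function(rois) {
  pet <- unlist(lapply(rois, function(r) r$data[1, , , ][r$in_grid]))
  has_ct <- dim(rois[[1]]$data)[1] > 1
  ct <- if (has_ct)
    unlist(lapply(rois, function(r) r$data[2, , , ][r$in_grid]))
  else pet
  s <- sd(pet)
  list(pet_mean = mean(pet), pet_sd = if (s > 1e-12) s else 1,
       ct_min = min(ct), ct_max = max(ct))
}

#' Conventional PET metabolic metrics
#'
#' SUVmax is the maximum SUV over the lesion mask. The metabolic tumor
#' volume (MTV) segmentation keeps mask voxels with SUV at or above
#' `mtv_threshold_fraction * SUVmax` (fixed-fraction convention, 41% by
#' default); SUVmean is the mean SUV over that segmentation, MTV its
#' volume in mL, and TLG = SUVmean x MTV.
#'
#' @param volume A [patient_volume()] with non-empty mask.
#' @param mtv_threshold_fraction Fraction of SUVmax delineating the MTV.
#' @return A `pet_metrics` list: `suv_max`, `suv_mean`, `mtv_ml`, `tlg`.
#' @examples
#' v <- patient_volume(array(c(2, 4, 6, 0), c(4, 1, 1)),
#'                     array(0, c(4, 1, 1)),
#'                     array(c(1, 1, 1, 0), c(4, 1, 1)),
#'                     spacing = c(10, 10, 10))
#' compute_pet_metrics(v, 0.41)
#' @export
compute_pet_metrics <- function(volume, mtv_threshold_fraction = 0.41) {
  stopifnot(inherits(volume, "patient_volume"),
            mtv_threshold_fraction >= 0, mtv_threshold_fraction <= 1)
  suv <- volume$pet[volume$mask > 0]
  if (length(suv) == 0) stop("empty lesion mask: no metrics to compute")
  suv_max <- max(suv)
  seg <- suv >= mtv_threshold_fraction * suv_max
  vox_ml <- prod(volume$spacing) / 1000
  mtv <- sum(seg) * vox_ml
  suv_mean <- mean(suv[seg])
  structure(list(suv_max = suv_max, suv_mean = suv_mean,
                 mtv_ml = mtv, tlg = suv_mean * mtv),
            class = "pet_metrics")
}

#' @export
print.pet_metrics <- function(x, ...) {
  cat(sprintf("SUVmax %.2f  SUVmean %.2f  MTV %.2f mL  TLG %.2f SUV*mL\n",
              x$suv_max, x$suv_mean, x$mtv_ml, x$tlg))
  invisible(x)
}

#' PET metrics table for a cohort
#'
#' @param cohort A [simulate_cohort()] result with volumes.
#' @param mtv_threshold_fraction Passed to [compute_pet_metrics()].
#' @return Data frame with one row per patient.
#' @export
pet_metrics_table <- function(cohort, mtv_threshold_fraction = 0.41) {
  rows <- lapply(cohort$patients, function(p) {
    m <- compute_pet_metrics(p$volume, mtv_threshold_fraction)
    data.frame(patient_id = p$patient_id, suv_max = m$suv_max,
               suv_mean = m$suv_mean, mtv_ml = m$mtv_ml, tlg = m$tlg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
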