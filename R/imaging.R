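#' A single-channel fluorescence image
#'
#' Wraps a non-negative 2-D or 3-D intensity array with its voxel (or
#' pixel) dimensions and a channel label. 2-D images and 3-D stacks are
#' treated identically throughout.
#'
#' @param intensity Numeric array (2-D matrix or 3-D array), all values
#'   >= 0.
#' @param voxel_dim Physical size of one voxel per axis, in micrometres
#'   (recycled to the array rank; default 1).
#' @param channel Channel label, e.g. a fluorophore name.
#' @return A `channel_image`.
#' @export
channel_image <- function(intensity, voxel_dim = 1, channel = "ch") {
  intensity <- as.array(intensity)
  nd <- length(dim(intensity))
  if (!nd %in% c(2L, 3L)) stop("intensity must be a 2-D or 3-D array")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  voxel_dim <- rep_len(as.numeric(voxel_dim), nd)
  if (any(voxel_dim <= 0)) stop("voxel dimensions must be positive")
  structure(list(intensity = intensity, voxel_dim = voxel_dim,
                 channel = channel),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("channel_image '%s': %s voxels, voxel %s um, range [%g, %g]\n",
              x$channel, paste(dim(x$intensity), collapse = " x "),
              paste(signif(x$voxel_dim, 3), collapse = " x "),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Voxel volume of a channel image
#'
#' @param img A `channel_image`.
#' @return Volume of one voxel in cubic micrometres (area for 2-D images).
#' @export
voxel_volume <- function(img) prod(img$voxel_dim)

#' Read / write a channel image as TIFF
#'
#' Single- or multi-page TIFF, one file per channel; pages become the
#' third array dimension. Intensities are rescaled from the TIFF [0, 1]
#' range by `scale` on read and into it on write.
#'
#' @param path TIFF path.
#' @param voxel_dim,channel Passed to [channel_image()].
#' @param scale Intensity full-scale (default 255).
#' @return `read_channel_tiff()`: a `channel_image`.
#' @export
read_channel_tiff <- function(path, voxel_dim = 1, channel = "ch",
                              scale = 255) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- if (length(pages) == 1L) {
    pages[[1]]
  } else {
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  channel_image(arr * scale, voxel_dim = voxel_dim, channel = channel)
}

#' @rdname read_channel_tiff
#' @param img A `channel_image` to write.
#' @return `write_channel_tiff()`: invisibly `path`.
#' @export
write_channel_tiff <- function(img, path, scale = 255) {
  arr <- img$intensity / scale
  if (max(arr) > 1) stop("intensities exceed full-scale; raise `scale`")
  if (length(dim(arr)) == 3L) {
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    tiff::writeTIFF(pages, path)
  } else {
    tiff::writeTIFF(arr, path)
  }
  invisible(path)
}

#' Threshold segmentation
#'
#' Marks voxels with intensity strictly greater than the threshold
#' (default 10, the absolute-intensity background filter used after
#' surface segmentation).
#'
#' @param img A `channel_image`.
#' @param threshold Absolute intensity threshold (default 10; strict `>`).
#' @return A `segmentation_mask`: logical array of the image's shape with
#'   attributes `threshold` and `voxel_dim`.
#' @export
segment_threshold <- function(img, threshold = 10) {
  mask <- img$intensity > threshold
  structure(mask, threshold = threshold, voxel_dim = img$voxel_dim,
            class = c("segmentation_mask", class(mask)))
}

#' Biovolume fraction of a target vs the general bacterial stain
#'
#' The image-based relative abundance: segmented biovolume of the
#' target-probe channel divided by the segmented biovolume of the general
#' bacterial (EUB338) channel. The voxel volume cancels in the ratio but
#' is accepted so absolute biovolumes can be reported alongside.
#'
#' @param target_mask,eub_mask Same-shape `segmentation_mask`s (or logical
#'   arrays).
#' @param voxel_volume Volume of one voxel in cubic micrometres (default 1).
#' @return A list with `fraction`, `target_biovolume`, `eub_biovolume`
#'   (volumes in cubic micrometres).
#' @export
biovolume_fraction <- function(target_mask, eub_mask, voxel_volume = 1) {
  if (!identical(dim(target_mask), dim(eub_mask))) {
    stop("masks must have identical shape")
  }
  n_eub <- sum(eub_mask)
  if (n_eub == 0) stop("no reference biomass: EUB mask is empty")
  n_target <- sum(target_mask)
  list(fraction = n_target / n_eub,
       target_biovolume = n_target * voxel_volume,
       eub_biovolume = n_eub * voxel_volume)
}

#' Thresholded Manders' co-localisation coefficients
#'
#' `M1` is the fraction of channel-1 intensity (over its above-threshold
#' voxels) that lies where channel 2 is above its threshold; `M2` is the
#' symmetric quantity for channel 2. Both range 0-1 when defined. Passing
#' `thr = 0` with strictly positive signal gives the unthresholded Manders
#' form. An empty above-threshold set makes the corresponding coefficient
#' undefined (`NA`, flagged).
#'
#' @param ch1,ch2 Same-shape `channel_image`s.
#' @param thr1,thr2 Per-channel absolute intensity thresholds (strict `>`;
#'   default 10).
#' @return A `manders_mcc`: list with `M1`, `M2` and `flags`.
#' @export
manders_mcc <- function(ch1, ch2, thr1 = 10, thr2 = 10) {
  a <- ch1$intensity
  b <- ch2$intensity
  if (!identical(dim(a), dim(b))) stop("channels must have identical shape")
  in1 <- a > thr1
  in2 <- b > thr2
  den1 <- sum(a[in1])
  den2 <- sum(b[in2])
  flags <- character(0)
  m1 <- if (den1 > 0) sum(a[in1 & in2]) / den1 else NA_real_
  m2 <- if (den2 > 0) sum(b[in1 & in2]) / den2 else NA_real_
  if (den1 == 0) flags <- c(flags, "channel 1 has no above-threshold signal")
  if (den2 == 0) flags <- c(flags, "channel 2 has no above-threshold signal")
  structure(list(M1 = m1, M2 = m2, flags = flags), class = "manders_mcc")
}

#' @export
print.manders_mcc <- function(x, ...) {
  cat(sprintf("Manders' MCC: M1 = %s, M2 = %s\n", fmt_frac(x$M1),
              fmt_frac(x$M2)))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Formamide dissociation curve
#'
#' @param formamide_pct Formamide concentrations in percent (unique,
#'   0-100).
#' @param mean_intensity Mean probe fluorescence intensity per
#'   concentration.
#' @param n_fields Fields of view averaged per point (default `NA`).
#' @return A `dissociation_curve` data frame sorted by formamide.
#' @export
dissociation_curve <- function(formamide_pct, mean_intensity,
                               n_fields = NA_integer_) {
  if (anyDuplicated(formamide_pct)) {
    stop("formamide concentrations must be unique")
  }
  if (any(formamide_pct < 0 | formamide_pct > 100)) {
    stop("formamide concentrations must be within 0-100%")
  }
  df <- data.frame(formamide_pct = as.numeric(formamide_pct),
                   mean_intensity = as.numeric(mean_intensity),
                   n_fields = rep_len(as.integer(n_fields),
                                      length(formamide_pct)))
  df <- df[order(df$formamide_pct), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dissociation_curve", "data.frame")
  df
}

#' Recommended formamide stringency from a dissociation curve
#'
#' Most-stringent-while-bright rule: the highest formamide concentration
#' whose mean intensity is still at least `retain_fraction` of the curve
#' maximum. The output is a recommendation to seed empirical optimisation,
#' not a substitute for it.
#'
#' @param curve A [dissociation_curve()] with at least 3 points.
#' @param retain_fraction Fraction of the maximum intensity that must be
#'   retained (default 0.9).
#' @return Recommended formamide concentration in percent.
#' @export
summarize_dissociation <- function(curve, retain_fraction = 0.9) {
  if (nrow(curve) < 3) stop("dissociation curve needs at least 3 points")
  cutoff <- retain_fraction * max(curve$mean_intensity)
  ok <- curve$mean_intensity >= cutoff
  max(curve$formamide_pct[ok])
}

#' Read / write a dissociation curve TSV
#'
#' Columns: `formamide_pct`, `mean_intensity`, `n_fields`.
#'
#' @param path TSV path.
#' @return `read_dissociation_curve()`: a `dissociation_curve`.
#' @export
read_dissociation_curve <- function(path) {
  df <- read_tsv(path)
  dissociation_curve(df$formamide_pct, df$mean_intensity,
                     df$n_fields %||% NA_integer_)
}

#' @rdname read_dissociation_curve
#' @param curve A `dissociation_curve` to write.
#' @return `write_dissociation_curve()`: invisibly `path`.
#' @export
write_dissociation_curve <- function(curve, path) {
  write_table(as.data.frame(curve), path, format = "tsv")
}
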