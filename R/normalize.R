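#' Intensity normalization statistics
#'
#' Two modes are supported, mirroring common practice for MR and CT
#' angiography:
#' * `mr_zscore` — each image is z-scored with its own mean and standard
#'   deviation, computed over all voxels at application time.
#' * `ct_clip_foreground` — intensities are clipped to the 0.5/99.5
#'   percentiles of the pooled foreground (vessel-labelled) voxels of the
#'   training images, then z-scored with the pooled foreground mean and
#'   standard deviation; these statistics are fit once and held constant at
#'   inference.
#'
#' Standard deviations use the population convention (divide by `n`), and a
#' degenerate sigma is floored at `1e-8` so constant patches normalize to
#' zero instead of erroring.
#'
#' @param images list of [image_volume()] training images.
#' @param masks for `ct_clip_foreground`, list of binary [seg_map()] masks
#'   aligned with `images`; ignored for `mr_zscore`.
#' @param mode `"mr_zscore"` or `"ct_clip_foreground"`.
#' @param clip_q clip quantiles for CT foreground (default `c(0.005, 0.995)`),
#'   linear interpolation between order statistics.
#' @return a `normalization_stats` object with fields `mode`, `clip_lo`,
#'   `clip_hi`, `mu`, `sigma`.
#' @export
fit_normalization <- function(images, masks = NULL,
                              mode = c("mr_zscore", "ct_clip_foreground"),
                              clip_q = c(0.005, 0.995)) {
  mode <- match.arg(mode)
  if (mode == "mr_zscore") {
    return(structure(list(mode = mode, clip_lo = NA_real_, clip_hi = NA_real_,
                          mu = NA_real_, sigma = NA_real_),
                     class = "normalization_stats"))
  }
  vt_validate(!is.null(masks) && length(masks) == length(images),
              "ct_clip_foreground requires one mask per image")
  fg <- unlist(lapply(seq_along(images), function(i) {
    images[[i]]$data[masks[[i]]$data > 0.5]
  }))
  if (length(fg) == 0L)
    vt_stop("empty foreground: no vessel-labelled voxels in any mask",
            "vt_validation_error")
  cl <- stats::quantile(fg, clip_q, names = FALSE, type = 7)
  fgc <- pmin(pmax(fg, cl[1]), cl[2])
  mu <- mean(fgc)
  sigma <- max(sqrt(mean((fgc - mu)^2)), 1e-8)
  structure(list(mode = mode, clip_lo = cl[1], clip_hi = cl[2],
                 mu = mu, sigma = sigma),
            class = "normalization_stats")
}

#' Apply intensity normalization
#'
#' For `mr_zscore` the image's own mean and (population) standard deviation
#' are used; for `ct_clip_foreground` the image is clipped to the stored
#' bounds and z-scored with the stored training statistics.
#'
#' @param vol an [image_volume()].
#' @param stats a `normalization_stats` from [fit_normalization()].
#' @return the normalized [image_volume()].
#' @export
normalize_volume <- function(vol, stats) {
  vt_validate(inherits(stats, "normalization_stats"),
              "`stats` must come from fit_normalization()")
  if (stats$mode == "mr_zscore") {
    mu <- mean(vol$data)
    sigma <- max(sqrt(mean((vol$data - mu)^2)), 1e-8)
    vol$data <- (vol$data - mu) / sigma
  } else {
    x <- pmin(pmax(vol$data, stats$clip_lo), stats$clip_hi)
    vol$data <- (x - stats$mu) / stats$sigma
  }
  vol
}

#' @export
print.normalization_stats <- function(x, ...) {
  cat(sprintf("<normalization_stats> mode=%s", x$mode))
  if (x$mode == "ct_clip_foreground")
    cat(sprintf(" clip=[%.4g, %.4g] mu=%.4g sigma=%.4g",
                x$clip_lo, x$clip_hi, x$mu, x$sigma))
  cat("\n")
  invisible(x)
}
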