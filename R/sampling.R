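#' Training patch sampler configuration
#'
#' The stochastic law for training subvolumes around ground-truth
#' centerlines. At a centerline point with local radius `R`, the cube side
#' is `L = R * alpha` with `alpha ~ N(mu_r, var_r)` and the cube center is
#' shifted off the centerline by `beta * R` along a random in-plane unit
#' vector, `beta ~ N(mu_s, var_s)`. The defaults `(mu_r, var_r) = (5, 1)` and
#' `(mu_s, var_s) = (0, 0.8)` make the mean sample five radii wide and
#' centered on the centerline. `alpha` draws below `alpha_min` are redrawn so
#' cube sides stay positive.
#'
#' @param mu_r,var_r mean and variance of the side-length multiplier.
#' @param mu_s,var_s mean and variance of the center shift (radius multiples).
#' @param samples_per_point subvolume draws per centerline point.
#' @param alpha_min redraw threshold for the side multiplier.
#' @param seed integer RNG seed used by [build_patch_dataset()].
#' @return a `sampler_config`.
#' @export
sampler_config <- function(mu_r = 5, var_r = 1, mu_s = 0, var_s = 0.8,
                           samples_per_point = 1L, alpha_min = 0.5, seed = 1L) {
  vt_validate(mu_r > 0, "`mu_r` must be positive")
  vt_validate(var_r >= 0 && var_s >= 0, "variances must be nonnegative")
  vt_validate(samples_per_point >= 1L, "`samples_per_point` must be >= 1")
  structure(list(mu_r = mu_r, var_r = var_r, mu_s = mu_s, var_s = var_s,
                 samples_per_point = as.integer(samples_per_point),
                 alpha_min = alpha_min, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Random unit vector perpendicular to a tangent
#'
#' Draws `w = (a u + b v) / ||a u + b v||` with `a, b ~ U[-1, 1]`, where
#' `u, v` is an orthonormal basis of the plane perpendicular to `tangent`.
#' A degenerate `a = b = 0` draw is redrawn. Uses the current RNG stream.
#'
#' @param tangent nonzero length-3 vector.
#' @return a unit length-3 vector orthogonal to `tangent`.
#' @export
perpendicular_unit_vector <- function(tangent) {
  tangent <- as.numeric(tangent)
  nt <- sqrt(sum(tangent^2))
  vt_validate(nt > 0, "`tangent` must be nonzero")
  t1 <- tangent / nt
  # any vector not parallel to t1 seeds the basis
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(t1, ref); u <- u / sqrt(sum(u^2))
  v <- cross3(t1, u)
  repeat {
    ab <- stats::runif(2, -1, 1)
    w <- ab[1] * u + ab[2] * v
    nw <- sqrt(sum(w^2))
    if (nw > 1e-12) return(w / nw)
  }
}

#' Draw one training subvolume spec at a centerline point
#'
#' @param C length-3 centerline point (mm).
#' @param R local vessel radius (mm, positive).
#' @param tangent local centerline tangent (nonzero).
#' @param cfg a [sampler_config()].
#' @return a [subvolume_spec()]. Uses the current RNG stream.
#' @export
sample_patch_spec <- function(C, R, tangent, cfg = sampler_config()) {
  vt_validate(is.numeric(R) && length(R) == 1L && R > 0, "`R` must be positive")
  repeat {
    alpha <- stats::rnorm(1, cfg$mu_r, sqrt(cfg$var_r))
    if (alpha > cfg$alpha_min) break
  }
  beta <- stats::rnorm(1, cfg$mu_s, sqrt(cfg$var_s))
  w <- perpendicular_unit_vector(tangent)
  subvolume_spec(center = as.numeric(C) + beta * R * w, side = R * alpha)
}

# Central-difference tangents along a polyline (forward/backward at the ends).
polyline_tangents <- function(points) {
  n <- nrow(points)
  if (n == 1L) return(matrix(c(1, 0, 0), ncol = 3))
  tg <- matrix(0, n, 3)
  tg[1, ] <- points[2, ] - points[1, ]
  tg[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2L) tg[2:(n - 1), ] <- points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE]
  tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
}

#' Build an image/label training patch dataset from a labelled case
#'
#' Walks every ground-truth centerline point, draws `samples_per_point`
#' subvolume specs from the sampler law, crops the image and the label mask,
#' and resamples both to a common patch grid (cubic interpolation for the
#' image, linear + 0.5 threshold for the label). Specs whose cube exits the
#' global volume are skipped and counted.
#'
#' @param case a `phantom_case`, or any list with `image` ([image_volume()]),
#'   `truth_mask` (binary [seg_map()]) and `truth_centerline`
#'   ([centerline_tree()] with per-point radii).
#' @param cfg a [sampler_config()]; its `seed` makes the dataset reproducible.
#' @param patch_grid_shape integer length-3 voxel shape of each output patch.
#' @param point_stride use every `point_stride`-th centerline point.
#' @return list with `pairs` (list of `list(image_patch, label_patch, spec)`)
#'   and `n_skipped`.
#' @export
build_patch_dataset <- function(case, cfg = sampler_config(),
                                patch_grid_shape = c(24L, 24L, 24L),
                                point_stride = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  pairs <- list()
  n_skipped <- 0L
  for (b in case$truth_centerline$branches) {
    tg <- polyline_tangents(b$points)
    idx <- seq(1L, nrow(b$points), by = point_stride)
    for (i in idx) {
      for (s in seq_len(cfg$samples_per_point)) {
        spec <- sample_patch_spec(b$points[i, ], b$radius[i], tg[i, ], cfg)
        img_patch <- tryCatch(extract_subvolume(case$image, spec),
                              vt_out_of_bounds = function(e) NULL)
        if (is.null(img_patch)) { n_skipped <- n_skipped + 1L; next }
        lab_patch <- extract_subvolume(case$truth_mask, spec)
        ip <- resample_to_shape(img_patch, patch_grid_shape, "image")
        lp <- resample_to_shape(seg_map(lab_patch$data, lab_patch$spacing,
                                        lab_patch$origin, binary = TRUE),
                                patch_grid_shape, "label")
        pairs[[length(pairs) + 1L]] <- list(image_patch = ip,
                                            label_patch = lp,
                                            spec = spec)
      }
    }
  }
  list(pairs = pairs, n_skipped = n_skipped)
}

# Resample a volume onto a fixed voxel shape spanning the same extent.
resample_to_shape <- function(vol, shape, kind) {
  d <- dim(vol$data)
  target <- d * vol$spacing / shape
  out <- resample_volume(vol, target, kind)
  # rounding in resample_volume can differ by one voxel; crop/grow deterministically
  if (!all(dim(out$data) == shape)) {
    od <- dim(out$data)
    take <- pmin(od, shape)
    arr <- array(if (kind == "label") 0 else out$data[1],
                 dim = shape)
    arr[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])] <-
      out$data[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])]
    out$data <- arr
  }
  out
}
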