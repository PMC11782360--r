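#' 3D scalar image volume
#'
#' The basic container for all volumetric data: a 3D array of scalars together
#' with the physical voxel spacing (mm/voxel per axis) and the physical
#' position of the first voxel (mm). The frame is axis-aligned: voxel
#' `(i, j, k)` (1-based) sits at `origin + (c(i, j, k) - 1) * spacing`.
#' Oblique orientation matrices are not modelled.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, mm per voxel along each axis; all positive.
#' @param origin numeric length-3, mm position of voxel (1,1,1).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vt_validate(is.array(data) && length(dim(data)) == 3L,
              "`data` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  vt_validate(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "`spacing` must be 3 positive finite numbers")
  vt_validate(length(origin) == 3L && all(is.finite(origin)),
              "`origin` must be 3 finite numbers")
  vt_validate(all(is.finite(data)), "voxel values must all be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Per-voxel segmentation map
#'
#' An [image_volume()] whose values are vessel probabilities in `[0, 1]`
#' (or a binary mask taking only values 0 and 1).
#'
#' @inheritParams image_volume
#' @param binary if `TRUE`, additionally require values in `{0, 1}`.
#' @return an object of class `seg_map` (also an `image_volume`).
#' @export
seg_map <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    binary = FALSE) {
  vol <- image_volume(data, spacing, origin)
  rng <- range(vol$data)
  vt_validate(rng[1] >= 0 && rng[2] <= 1,
              "segmentation values must lie in [0, 1]")
  if (binary)
    vt_validate(all(vol$data %in% c(0, 1)), "binary map must take values in {0, 1}")
  class(vol) <- c("seg_map", "image_volume")
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%s) mm, origin (%s) mm\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert between voxel indices and physical coordinates
#'
#' `voxel_to_world()` maps (possibly fractional) 1-based voxel indices to mm;
#' `world_to_voxel()` is its exact inverse and returns fractional indices.
#'
#' @param vol an [image_volume()].
#' @param ijk,xyz numeric length-3 vector or n-by-3 matrix.
#' @return a vector or matrix of the same shape.
#' @export
voxel_to_world <- function(vol, ijk) {
  if (is.matrix(ijk))
    sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  else vol$origin + (as.numeric(ijk) - 1) * vol$spacing
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  if (is.matrix(xyz))
    sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  else (as.numeric(xyz) - vol$origin) / vol$spacing + 1
}

#' Voxel-center coordinate grids
#' @keywords internal
axis_coords <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Trilinear interpolation of a volume at physical points
#'
#' Values are clamped to the grid edge (nearest-cell extension) so that points
#' marginally outside the volume remain usable during gradient descent.
#'
#' @param vol an [image_volume()].
#' @param xyz n-by-3 matrix (or length-3 vector) of mm points.
#' @return numeric vector of interpolated values.
#' @export
interp_trilinear <- function(vol, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  idx <- world_to_voxel(vol, xyz)
  cpp_trilinear(vol$data, idx)
}

#' Separable Gaussian smoothing of a volume
#'
#' Smooths with a Gaussian kernel of physical standard deviation `sigma_mm`
#' along each axis (truncated at 3 sigma), with replicate edge handling.
#' `sigma_mm = 0` returns the input unchanged.
#'
#' @param vol an [image_volume()].
#' @param sigma_mm Gaussian sigma in mm (scalar).
#' @return the smoothed [image_volume()].
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  vt_validate(is.numeric(sigma_mm) && length(sigma_mm) == 1L && sigma_mm >= 0,
              "`sigma_mm` must be a single nonnegative number")
  if (sigma_mm == 0) return(vol)
  out <- vol$data
  for (a in 1:3) {
    s <- sigma_mm / vol$spacing[a]
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-rad):rad / s)^2)
    k <- k / sum(k)
    out <- convolve_axis(out, k, a)
  }
  vol$data <- out
  vol
}

# 1D convolution along axis `a` with replicate padding, vectorised by
# permuting the target axis to the front and shifting whole matrices.
convolve_axis <- function(arr, kernel, a) {
  perm <- c(a, setdiff(1:3, a))
  x <- aperm(arr, perm)
  d <- dim(x)
  m <- matrix(x, nrow = d[1])
  rad <- (length(kernel) - 1L) / 2L
  n <- d[1]
  acc <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - 1L - rad
    rows <- pmin(pmax(seq_len(n) + off, 1L), n)
    acc <- acc + kernel[j] * m[rows, , drop = FALSE]
  }
  y <- array(acc, dim = d)
  aperm(y, order(perm))
}
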