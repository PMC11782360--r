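#' Cubic subvolume specification
#'
#' An axis-aligned cube in physical coordinates: a center point and a side
#' length, both in mm. This is the unit the patch sampler emits and the
#' tracer consumes.
#'
#' @param center numeric length-3, mm.
#' @param side cube side length, mm, positive.
#' @return a `subvolume_spec`.
#' @export
subvolume_spec <- function(center, side) {
  center <- as.numeric(center)
  vt_validate(length(center) == 3L && all(is.finite(center)),
              "`center` must be 3 finite numbers")
  vt_validate(is.numeric(side) && length(side) == 1L && is.finite(side) && side > 0,
              "`side` must be a single positive number")
  structure(list(center = center, side = side), class = "subvolume_spec")
}

#' Resample a volume to a new spacing
#'
#' Images are resampled with cubic (Catmull-Rom) interpolation; label maps
#' are resampled by linear interpolation of their one-hot encoding followed
#' by argmax (for a binary map this reduces to linear interpolation and a
#' 0.5 threshold), so label outputs remain crisp label values. The output
#' grid covers the same physical extent, with the new voxel-center lattice
#' centered on the old one.
#'
#' @param vol an [image_volume()] (or [seg_map()] for `kind = "label"`).
#' @param target_spacing numeric length-3 (or scalar, recycled), mm/voxel.
#' @param kind `"image"` or `"label"`.
#' @return the resampled volume, same class as the input.
#' @export
resample_volume <- function(vol, target_spacing, kind = c("image", "label")) {
  kind <- match.arg(kind)
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  vt_validate(all(is.finite(target_spacing)) && all(target_spacing > 0),
              "`target_spacing` must be positive")
  d <- dim(vol$data)
  n_new <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  origin_new <- vol$origin + ((d - 1) * vol$spacing - (n_new - 1) * target_spacing) / 2
  ax <- lapply(1:3, function(a)
    (origin_new[a] + (seq_len(n_new[a]) - 1) * target_spacing[a] - vol$origin[a]) /
      vol$spacing[a] + 1)
  idx <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  if (kind == "image") {
    vals <- cpp_interp(vol$data, d, idx, 3L)
    out <- array(vals, dim = n_new)
  } else {
    levels <- sort(unique(as.vector(vol$data)))
    if (length(levels) <= 2L && all(levels %in% c(0, 1))) {
      vals <- cpp_interp(vol$data, d, idx, 1L)
      out <- array(as.numeric(vals >= 0.5), dim = n_new)
    } else {
      scores <- vapply(levels, function(lv)
        cpp_interp(array(as.numeric(vol$data == lv), dim = d), d, idx, 1L),
        numeric(nrow(idx)))
      out <- array(levels[max.col(scores, ties.method = "last")], dim = n_new)
    }
  }
  res <- vol
  res$data <- out
  res$spacing <- target_spacing
  res$origin <- origin_new
  res
}

#' Extract a cubic subvolume from a global volume
#'
#' Crops the voxels whose centers fall in the axis-aligned cube
#' `[center - side/2, center + side/2]^3`. No resampling or padding is done:
#' the crop stays on the parent voxel lattice. If the cube extends outside
#' the global volume by more than `max_outside_fraction` of its volume (the
#' default 0 means any protrusion), an out-of-bounds condition is signalled —
#' this is the tracer's "requesting image data that does not exist" stop.
#'
#' @param vol an [image_volume()].
#' @param spec a [subvolume_spec()].
#' @param max_outside_fraction allowed fraction of the cube volume lying
#'   outside the global volume before the extraction errors.
#' @return an [image_volume()] crop with attributes `outside_fraction` and
#'   `index_range` (2-by-3 matrix of 1-based parent indices).
#' @export
extract_subvolume <- function(vol, spec, max_outside_fraction = 0) {
  vt_validate(inherits(spec, "subvolume_spec"), "`spec` must be a subvolume_spec")
  d <- dim(vol$data)
  lo_mm <- spec$center - spec$side / 2
  hi_mm <- spec$center + spec$side / 2
  # physical extent of the voxel grid (voxel edges)
  ext_lo <- vol$origin - vol$spacing / 2
  ext_hi <- vol$origin + (d - 0.5) * vol$spacing
  overlap <- pmax(0, pmin(hi_mm, ext_hi) - pmax(lo_mm, ext_lo))
  outside_fraction <- 1 - prod(overlap) / spec$side^3
  if (prod(overlap) <= 0)
    vt_stop("requested subvolume lies entirely outside the image",
            "vt_out_of_bounds", outside_fraction = 1)
  if (outside_fraction > max_outside_fraction + 1e-12)
    vt_stop(sprintf("subvolume extends outside the image (%.1f%% of the cube)",
                    100 * outside_fraction),
            "vt_out_of_bounds", outside_fraction = outside_fraction)
  lo <- pmax(1L, as.integer(ceiling((lo_mm - vol$origin) / vol$spacing + 1 - 1e-9)))
  hi <- pmin(d, as.integer(floor((hi_mm - vol$origin) / vol$spacing + 1 + 1e-9)))
  if (any(hi < lo))
    vt_stop("requested subvolume contains no voxel centers", "vt_out_of_bounds",
            outside_fraction = outside_fraction)
  crop <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- image_volume(crop, spacing = vol$spacing,
                      origin = voxel_to_world(vol, lo))
  attr(out, "outside_fraction") <- outside_fraction
  attr(out, "index_range") <- rbind(lo, hi)
  out
}
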