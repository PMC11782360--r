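#' Synthetic vascular tree specification
#'
#' Describes a tree of straight tube segments ("branches"), each modelled as
#' a capsule: a cylinder of constant radius with hemispherical end caps, so
#' junctions between a parent and its children are watertight. The rendered
#' image is a two-level intensity model (inside/outside), optionally blurred
#' with a Gaussian of physical width `blur_sigma` and corrupted with additive
#' Gaussian noise — the minimal model that reproduces the blurred, ambiguous
#' vessel boundaries that make local segmentation hard in real angiography.
#'
#' @param branches list; each element a list with `start`, `end` (length-3 mm),
#'   `radius` (mm, positive) and `parent` (index of parent branch, or `NA` for
#'   a root). Every child's start point must lie on its parent's axis segment
#'   within one voxel.
#' @param intensity_inside,intensity_outside the two intensity levels.
#' @param blur_sigma Gaussian blur sigma in mm (>= 0).
#' @param noise_sigma additive Gaussian noise sigma in intensity units (>= 0).
#' @param spacing mm/voxel (scalar or length 3).
#' @param margin_mm clearance added around the tree bounding box beyond the
#'   largest radius; scalar or per-axis length 3. Transverse margins must
#'   leave room for tracing subvolumes (about 2.5 local radii); a small
#'   margin along a vessel's axis makes tracing terminate at the volume
#'   face.
#' @param seed integer RNG seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return a `tree_spec`.
#' @export
tree_spec <- function(branches, intensity_inside = 1, intensity_outside = 0,
                      blur_sigma = 0.5, noise_sigma = 0.05,
                      spacing = 0.5, margin_mm = 2, seed = 1L) {
  vt_validate(is.list(branches) && length(branches) >= 1L,
              "`branches` must be a nonempty list")
  spacing <- rep_len(as.numeric(spacing), 3L)
  margin_mm <- rep_len(as.numeric(margin_mm), 3L)
  vt_validate(all(spacing > 0), "`spacing` must be positive")
  vt_validate(blur_sigma >= 0 && noise_sigma >= 0,
              "`blur_sigma` and `noise_sigma` must be nonnegative")
  branches <- lapply(branches, function(b) {
    vt_validate(is.numeric(b$radius) && length(b$radius) == 1L && b$radius > 0,
                "branch radius must be a single positive number")
    list(start = as.numeric(b$start), end = as.numeric(b$end),
         radius = as.numeric(b$radius),
         parent = if (is.null(b$parent) || is.na(b$parent)) NA_integer_
                  else as.integer(b$parent))
  })
  for (i in seq_along(branches)) {
    p <- branches[[i]]$parent
    if (is.na(p)) next
    vt_validate(p >= 1L && p < i,
                sprintf("branch %d has a dangling parent index %d", i, p))
    d <- point_segment_distance(matrix(branches[[i]]$start, ncol = 3),
                                branches[[p]]$start, branches[[p]]$end)
    vt_validate(d <= max(spacing),
                sprintf("branch %d does not start on its parent's axis", i))
  }
  structure(list(branches = branches,
                 intensity_inside = intensity_inside,
                 intensity_outside = intensity_outside,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 spacing = spacing, margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "tree_spec")
}

point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(pts, 2, a)
  t <- if (len2 > 0) pmin(pmax(as.vector(rel %*% ab) / len2, 0), 1) else 0
  proj <- outer(t, ab)
  sqrt(rowSums((rel - proj)^2))
}

#' Render a phantom image with exact ground truth
#'
#' Voxelizes the capsule union of a [tree_spec()] at voxel centers (a voxel
#' is foreground iff its center lies inside some capsule), renders the
#' two-level intensity image, applies Gaussian blur and additive noise, and
#' returns the image together with the unblurred binary truth mask and the
#' analytic branch-axis centerlines with per-point radius.
#'
#' @param spec a [tree_spec()].
#' @return a `phantom_case`: list with `image` ([image_volume()]),
#'   `truth_mask` (binary [seg_map()]), `truth_centerline`
#'   ([centerline_tree()]) and the generating `spec`.
#' @export
make_phantom <- function(spec) {
  vt_validate(inherits(spec, "tree_spec"), "`spec` must come from tree_spec()")
  allpts <- do.call(rbind, lapply(spec$branches, function(b) rbind(b$start, b$end)))
  radii <- vapply(spec$branches, function(b) b$radius, numeric(1))
  lo <- apply(allpts, 2, min) - max(radii) - spec$margin_mm
  hi <- apply(allpts, 2, max) + max(radii) + spec$margin_mm
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  origin <- lo
  mask <- array(FALSE, dim = dims)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spec$spacing[a])
  for (b in spec$branches) {
    # restrict the distance test to the capsule's bounding sub-grid
    blo <- pmin(b$start, b$end) - b$radius
    bhi <- pmax(b$start, b$end) + b$radius
    ir <- lapply(1:3, function(a) which(ax[[a]] >= blo[a] - spec$spacing[a] &
                                          ax[[a]] <= bhi[a] + spec$spacing[a]))
    if (any(vapply(ir, length, integer(1)) == 0L)) next
    g <- as.matrix(expand.grid(ax[[1]][ir[[1]]], ax[[2]][ir[[2]]], ax[[3]][ir[[3]]],
                               KEEP.OUT.ATTRS = FALSE))
    inside <- point_segment_distance(g, b$start, b$end) <= b$radius
    mask[ir[[1]], ir[[2]], ir[[3]]] <-
      mask[ir[[1]], ir[[2]], ir[[3]]] | array(inside, dim = vapply(ir, length, integer(1)))
  }
  ind <- array(as.numeric(mask), dim = dims)
  img_data <- ind * spec$intensity_inside + (1 - ind) * spec$intensity_outside
  img <- image_volume(img_data, spacing = spec$spacing, origin = origin)
  if (spec$blur_sigma > 0) img <- gaussian_smooth(img, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(spec$seed)
    img$data <- img$data + array(stats::rnorm(prod(dims), sd = spec$noise_sigma),
                                 dim = dims)
  }
  step <- min(spec$spacing) / 2
  branches <- lapply(spec$branches, function(b) {
    rp <- resample_polyline(rbind(b$start, b$end), step)
    list(points = rp$points, radius = rep(b$radius, nrow(rp$points)))
  })
  has_child <- rep(FALSE, length(spec$branches))
  for (b in spec$branches) if (!is.na(b$parent)) has_child[b$parent] <- TRUE
  leafs <- which(!has_child)
  targets <- do.call(rbind, lapply(spec$branches[leafs], function(b) b$end))
  tree <- centerline_tree(branches,
                          source = spec$branches[[1]]$start,
                          target_points = targets)
  structure(list(image = img,
                 truth_mask = seg_map(ind, spacing = spec$spacing,
                                      origin = origin, binary = TRUE),
                 truth_centerline = tree,
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case>\n  image: "); print(x$image)
  cat(sprintf("  foreground voxels: %d\n  ", sum(x$truth_mask$data)))
  print(x$truth_centerline)
  invisible(x)
}

#' Standard phantom suite
#'
#' Five named tubular geometries exercising the tracer's behaviours:
#' a straight tube, a 90-degree bend, a symmetric Y-bifurcation, an
#' asymmetric tree with a thin side branch (radius ratio > 3:1), and a
#' tapering tube whose distal radius drops below the 0.5 mm minimum-radius
#' stop criterion.
#'
#' @param spacing mm/voxel for every case.
#' @param blur_sigma,noise_sigma image degradation shared by every case.
#' @return named list of `phantom_case` objects.
#' @export
make_standard_suite <- function(spacing = 0.5, blur_sigma = 0.5,
                                noise_sigma = 0.05) {
  mk <- function(branches, seed, margin)
    make_phantom(tree_spec(branches, blur_sigma = blur_sigma,
                           noise_sigma = noise_sigma, spacing = spacing,
                           margin_mm = margin, seed = seed))
  list(
    straight = mk(list(
      list(start = c(0, 0, 0), end = c(40, 0, 0), radius = 2, parent = NA)),
      seed = 101L, margin = c(0.5, 5, 5)),
    bend90 = mk(list(
      list(start = c(0, 0, 0), end = c(20, 0, 0), radius = 2, parent = NA),
      list(start = c(20, 0, 0), end = c(20, 20, 0), radius = 2, parent = 1)),
      seed = 102L, margin = c(4, 4, 4)),
    y_bifurcation = mk(list(
      list(start = c(0, 0, 0), end = c(18, 0, 0), radius = 2.5, parent = NA),
      list(start = c(18, 0, 0), end = c(34, 11, 0), radius = 1.8, parent = 1),
      list(start = c(18, 0, 0), end = c(34, -11, 0), radius = 1.8, parent = 1)),
      seed = 103L, margin = c(0.25, 5, 5)),
    asymmetric_tree = mk(list(
      list(start = c(0, 0, 0), end = c(36, 0, 0), radius = 3.6, parent = NA),
      list(start = c(18, 0, 0), end = c(28, 12, 0), radius = 1.2, parent = 1)),
      seed = 104L, margin = c(2, 6, 6)),
    tapering = mk(list(
      list(start = c(0, 0, 0), end = c(10, 0, 0), radius = 2.2, parent = NA),
      list(start = c(10, 0, 0), end = c(16, 0, 0), radius = 1.6, parent = 1),
      list(start = c(16, 0, 0), end = c(22, 0, 0), radius = 1.2, parent = 2),
      list(start = c(22, 0, 0), end = c(28, 0, 0), radius = 0.9, parent = 3),
      list(start = c(28, 0, 0), end = c(33, 0, 0), radius = 0.65, parent = 4),
      list(start = c(33, 0, 0), end = c(38, 0, 0), radius = 0.4, parent = 5)),
      seed = 105L, margin = c(3, 4.5, 4.5))
  )
}

#' Analytic capsule-union volume of a tree spec (single branch exact)
#'
#' For a single branch the capsule volume is
#' `pi r^2 |b - a| + 4/3 pi r^3` exactly; for multi-branch trees the sum
#' over-counts junction overlaps and is an upper bound.
#'
#' @param spec a [tree_spec()].
#' @return volume in mm^3.
#' @export
capsule_volume <- function(spec) {
  sum(vapply(spec$branches, function(b) {
    len <- sqrt(sum((b$end - b$start)^2))
    pi * b$radius^2 * len + 4 / 3 * pi * b$radius^3
  }, numeric(1)))
}
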