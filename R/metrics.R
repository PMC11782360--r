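#' Dice overlap between two binary segmentations
#'
#' Identical to the soft Dice used in training ([dice_score()]) evaluated on
#' binary maps: `D = 2 |X & Y| / (|X| + |Y|)`.
#'
#' @param X,Y binary [seg_map()]s (or arrays) on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice_metric <- function(X, Y) dice_score(X, Y)

# Boundary voxels: foreground voxels with at least one 6-neighbour outside
# the foreground (voxels on the array edge count as boundary).
boundary_voxels <- function(mask) {
  m <- if (inherits(mask, "image_volume")) mask$data > 0.5 else mask > 0.5
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(inner & !nb, arr.ind = TRUE)
}

#' Hausdorff distance between two segmentations
#'
#' `H(X, Y) = max(d(X, Y), d(Y, X))` with `d` the directed Hausdorff
#' distance `sup_x inf_y ||x - y||`, measured between the *boundary* voxel
#' centers of the two masks (the distance between the two surfaces) and
#' reported in voxel units of the evaluation grid. Computed exactly via the
#' Euclidean distance transform of each boundary set.
#'
#' @param X,Y nonempty binary [seg_map()]s (or arrays) on the same grid.
#' @return nonnegative scalar (voxels); 0 iff the boundaries coincide.
#' @export
hausdorff_metric <- function(X, Y) {
  a <- as_seg_data(X, Y)
  dx <- if (inherits(X, "image_volume")) dim(X$data) else dim(X)
  bx <- boundary_voxels(X)
  by <- boundary_voxels(Y)
  if (nrow(bx) == 0L || nrow(by) == 0L)
    vt_stop("Hausdorff distance is undefined for an empty mask",
            "vt_validation_error")
  directed <- function(from, to_set) {
    # exact nearest-boundary-point distances via EDT of the target set
    ind <- array(1, dim = dx)
    ind[to_set] <- 0
    dt <- cpp_edt(ind, dx, c(1, 1, 1)) # voxel units
    max(dt[from])
  }
  max(directed(bx, by), directed(by, bx))
}

#' Centerline overlap of a segmentation
#'
#' The fraction of ground-truth centerline length captured by the predicted
#' segmentation: each branch is resampled at a fixed arclength step (half
#' the minimum voxel spacing), and the overlap is the fraction of sample
#' points whose nearest voxel is foreground — a quadrature of
#' `CO = integral_C Y dx / integral_C dx` with error bounded by one step.
#'
#' @param Y binary [seg_map()].
#' @param centerline a [centerline_tree()] in the same physical frame.
#' @return scalar in `[0, 1]`.
#' @export
centerline_overlap <- function(Y, centerline) {
  vt_validate(inherits(centerline, "centerline_tree"),
              "`centerline` must be a centerline_tree")
  vt_validate(length(centerline$branches) > 0, "empty centerline")
  step <- min(Y$spacing) / 2
  d <- dim(Y$data)
  total <- 0L; inside <- 0L
  for (b in centerline$branches) {
    rp <- resample_polyline(b$points, step)
    idx <- round(world_to_voxel(Y, rp$points))
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
      idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    vals <- numeric(nrow(idx))
    if (any(ok))
      vals[ok] <- Y$data[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
    total <- total + nrow(idx)
    inside <- inside + sum(vals > 0.5)
  }
  inside / total
}

#' Six-radius centerline evaluation mask
#'
#' The evaluation region used to score predictions against partially
#' annotated ground truth: a voxel belongs to the mask iff its distance to
#' some centerline point `p` is at most `n_radii` times the local radius at
#' `p` (default six). Masking both prediction and truth with this region
#' excludes unannotated vasculature from the metrics.
#'
#' @param ref an [image_volume()] defining the evaluation grid.
#' @param centerline a [centerline_tree()] with per-point radii.
#' @param n_radii distance allowance in local-radius multiples.
#' @return binary [seg_map()] on the grid of `ref`.
#' @export
evaluation_mask <- function(ref, centerline, n_radii = 6) {
  d <- dim(ref$data)
  ax <- axis_coords(ref)
  out <- array(FALSE, d)
  step <- min(ref$spacing)
  for (b in centerline$branches) {
    rp <- resample_polyline(b$points, step, scalar = b$radius)
    pts <- rp$points; rad <- rp$scalar
    for (i in seq_len(nrow(pts))) {
      r <- n_radii * rad[i]
      ir <- lapply(1:3, function(a)
        which(ax[[a]] >= pts[i, a] - r & ax[[a]] <= pts[i, a] + r))
      if (any(vapply(ir, length, integer(1)) == 0L)) next
      sub <- outer(outer((ax[[1]][ir[[1]]] - pts[i, 1])^2,
                         (ax[[2]][ir[[2]]] - pts[i, 2])^2, "+"),
                   (ax[[3]][ir[[3]]] - pts[i, 3])^2, "+") <= r^2
      out[ir[[1]], ir[[2]], ir[[3]]] <- out[ir[[1]], ir[[2]], ir[[3]]] | sub
    }
  }
  seg_map(array(as.numeric(out), d), ref$spacing, ref$origin, binary = TRUE)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Computes Dice, Hausdorff distance (voxels) and centerline overlap,
#' optionally restricted to the six-radius evaluation region around the
#' ground-truth centerline.
#'
#' @param pred predicted binary [seg_map()].
#' @param truth ground-truth binary [seg_map()] on the same grid.
#' @param centerline ground-truth [centerline_tree()].
#' @param mask_six_radius if `TRUE`, mask both maps with
#'   [evaluation_mask()] before scoring.
#' @return an `eval_report`: list with `dice`, `hausdorff`,
#'   `centerline_overlap`, `masked`.
#' @export
evaluate_segmentation <- function(pred, truth, centerline,
                                  mask_six_radius = FALSE) {
  vt_validate(same_grid(pred, truth), "prediction and truth grids differ")
  if (mask_six_radius) {
    m <- evaluation_mask(truth, centerline)
    pred <- seg_map(pred$data * m$data, pred$spacing, pred$origin)
    truth <- seg_map(truth$data * m$data, truth$spacing, truth$origin)
  }
  structure(list(dice = dice_metric(pred, truth),
                 hausdorff = hausdorff_metric(pred, truth),
                 centerline_overlap = centerline_overlap(pred, centerline),
                 masked = mask_six_radius),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report%s> Dice %.4f | Hausdorff %.2f voxels | centerline overlap %.4f\n",
              if (x$masked) ", six-radius masked" else "",
              x$dice, x$hausdorff, x$centerline_overlap))
  invisible(x)
}
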