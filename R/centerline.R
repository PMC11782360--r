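#' Centerline tree
#'
#' A set of branch polylines in physical coordinates with a per-point radius.
#' Points along each branch are ordered from the source (proximal) end toward
#' the target (distal) end. The optional `source` is the proximal seed point
#' of the tree; `target_points` are the distal endpoints (one per branch for
#' locally-extracted centerlines, the leaf endpoints for phantom truth trees).
#'
#' @param branches list; each element a list with `points` (n-by-3 matrix, mm)
#'   and `radius` (length-n positive numeric).
#' @param source optional length-3 source point (mm).
#' @param target_points optional k-by-3 matrix of distal endpoints (mm).
#' @return a `centerline_tree`.
#' @export
centerline_tree <- function(branches, source = NULL, target_points = NULL) {
  vt_validate(is.list(branches) && length(branches) >= 1L,
              "`branches` must be a nonempty list")
  branches <- lapply(branches, function(b) {
    pts <- b$points
    if (!is.matrix(pts)) pts <- matrix(as.numeric(pts), ncol = 3)
    rad <- as.numeric(b$radius)
    vt_validate(ncol(pts) == 3L && nrow(pts) >= 1L, "branch points must be n-by-3")
    vt_validate(length(rad) == nrow(pts) && all(rad > 0),
                "branch radius must be positive and match the point count")
    list(points = pts, radius = rad)
  })
  if (is.null(target_points))
    target_points <- do.call(rbind, lapply(branches, function(b)
      b$points[nrow(b$points), , drop = FALSE]))
  structure(list(branches = branches, source = source,
                 target_points = target_points),
            class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  npts <- sum(vapply(x$branches, function(b) nrow(b$points), integer(1)))
  cat(sprintf("<centerline_tree> %d branch(es), %d points, %d target endpoint(s)\n",
              length(x$branches), npts, nrow(x$target_points)))
  invisible(x)
}

#' Total arclength of every branch in a centerline tree
#' @param tree a [centerline_tree()].
#' @return numeric vector of per-branch arclengths (mm).
#' @export
branch_lengths <- function(tree) {
  vapply(tree$branches, function(b) {
    if (nrow(b$points) < 2L) return(0)
    sum(sqrt(rowSums(diff(b$points)^2)))
  }, numeric(1))
}

# Resample a polyline at (approximately) equal arclength steps, linearly
# interpolating positions and any per-point scalar.
resample_polyline <- function(points, step, scalar = NULL) {
  if (nrow(points) < 2L) {
    return(list(points = points, scalar = scalar,
                s = 0))
  }
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(list(points = points[1, , drop = FALSE],
                              scalar = if (!is.null(scalar)) scalar[1], s = 0))
  ns <- max(2L, ceiling(total / step) + 1L)
  si <- seq(0, total, length.out = ns)
  pts <- vapply(1:3, function(a) stats::approx(s, points[, a], xout = si)$y,
                numeric(ns))
  out <- list(points = matrix(pts, ncol = 3), s = si)
  if (!is.null(scalar)) out$scalar <- stats::approx(s, scalar, xout = si)$y
  out
}
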