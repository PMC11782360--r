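#' Fusion configuration for global assembly
#'
#' Controls how overlapping local predictions are fused into the global
#' probability map and turned into a final surface: the Gaussian weight
#' width as a fraction of the subvolume side (`sigma = sigma_fraction * L`),
#' the binarization threshold, the connectivity used to keep the largest
#' connected body, and the mesh smoothing schedule (windowed-sinc family
#' smoothing, ten iterations at passband 0.01).
#'
#' @param sigma_fraction Gaussian sigma as a fraction of the cube side.
#' @param threshold binarization threshold `t` (voxels with fused value
#'   `>= t` are kept).
#' @param connectivity 26 or 6, for the largest-component filter.
#' @param smooth_iterations,passband mesh smoothing schedule.
#' @return a `fusion_config`.
#' @export
fusion_config <- function(sigma_fraction = 1 / 4, threshold = 0.5,
                          connectivity = 26L, smooth_iterations = 10L,
                          passband = 0.01) {
  vt_validate(sigma_fraction > 0, "`sigma_fraction` must be positive")
  vt_validate(threshold > 0 && threshold < 1, "`threshold` must be in (0, 1)")
  vt_validate(connectivity %in% c(6L, 26L), "`connectivity` must be 6 or 26")
  structure(list(sigma_fraction = sigma_fraction, threshold = threshold,
                 connectivity = as.integer(connectivity),
                 smooth_iterations = as.integer(smooth_iterations),
                 passband = passband),
            class = "fusion_config")
}

#' Global prediction accumulator
#'
#' Running Gaussian-weighted sums over the global image grid: a
#' weighted-sum grid, a weight-sum grid, and a per-voxel visit count. The
#' fused value at a voxel is the weighted mean `sum(w * s) / sum(w)` of all
#' local predictions `s` that covered it, so any number of overlapping cubes
#' all predicting a constant `c` fuse to exactly `c`.
#'
#' @param ref_vol an [image_volume()] defining the global grid.
#' @param cfg a [fusion_config()].
#' @return a `global_accumulator`.
#' @export
global_accumulator <- function(ref_vol, cfg = fusion_config()) {
  d <- dim(ref_vol$data)
  structure(list(wsum = array(0, d), w = array(0, d),
                 visits = array(0L, d),
                 spacing = ref_vol$spacing, origin = ref_vol$origin,
                 cfg = cfg),
            class = "global_accumulator")
}

#' Gaussian fusion weight map for a subvolume
#'
#' Weights fall off with distance from the subvolume center as
#' `w = exp(-d^2 / sigma^2)` with `sigma = L/4`: the center voxel gets
#' weight 1 and a voxel at two standard deviations (e.g. a face center at
#' `d = L/2`) gets `exp(-4)`, approximately 0.02, down-weighting the less
#' reliable predictions near subvolume borders.
#'
#' @param patch an [image_volume()] on the subvolume grid (values unused).
#' @param spec the [subvolume_spec()] the patch was cut with.
#' @param sigma_fraction sigma as a fraction of the side length.
#' @return numeric array of weights in `(0, 1]`, same shape as `patch`.
#' @export
weight_map <- function(patch, spec, sigma_fraction = 1 / 4) {
  sigma <- sigma_fraction * spec$side
  ax <- axis_coords(patch)
  d2x <- (ax[[1]] - spec$center[1])^2
  d2y <- (ax[[2]] - spec$center[2])^2
  d2z <- (ax[[3]] - spec$center[3])^2
  d2 <- outer(outer(d2x, d2y, "+"), d2z, "+")
  exp(-d2 / sigma^2)
}

#' Evaluate the fusion weight kernel at a given distance
#'
#' @param d distance from the subvolume center (mm).
#' @param L subvolume side length (mm).
#' @param sigma_fraction sigma as a fraction of `L`.
#' @return the weight `exp(-d^2 / sigma^2)` with `sigma = sigma_fraction * L`.
#' @export
fusion_weight <- function(d, L, sigma_fraction = 1 / 4) {
  sigma <- sigma_fraction * L
  exp(-(d^2) / sigma^2)
}

#' Fuse a local prediction into the global accumulator
#'
#' @param acc a [global_accumulator()].
#' @param local_map [seg_map()] prediction on a subvolume grid that lies on
#'   the global voxel lattice (as produced by [extract_subvolume()]).
#' @param spec the [subvolume_spec()] of the local map.
#' @return the updated accumulator.
#' @export
accumulate <- function(acc, local_map, spec) {
  vt_validate(inherits(acc, "global_accumulator"), "`acc` must be an accumulator")
  vt_validate(all(abs(local_map$spacing - acc$spacing) < 1e-9),
              "local map is not on the global voxel lattice")
  offs <- (local_map$origin - acc$origin) / acc$spacing
  vt_validate(all(abs(offs - round(offs)) < 1e-6),
              "local map origin is not aligned with the global lattice")
  lo <- as.integer(round(offs)) + 1L
  d <- dim(local_map$data)
  hi <- lo + d - 1L
  vt_validate(all(lo >= 1L) && all(hi <= dim(acc$wsum)),
              "local map extends outside the global grid")
  w <- weight_map(local_map, spec, acc$cfg$sigma_fraction)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  acc$wsum[ix, iy, iz] <- acc$wsum[ix, iy, iz] + w * local_map$data
  acc$w[ix, iy, iz] <- acc$w[ix, iy, iz] + w
  acc$visits[ix, iy, iz] <- acc$visits[ix, iy, iz] + 1L
  acc
}

#' Fused probability map of an accumulator
#'
#' The weighted mean prediction where at least one subvolume contributed,
#' and 0 elsewhere.
#'
#' @param acc a [global_accumulator()].
#' @return a [seg_map()] on the global grid.
#' @export
fused_map <- function(acc) {
  y <- array(0, dim = dim(acc$wsum))
  covered <- acc$w > 0
  y[covered] <- acc$wsum[covered] / acc$w[covered]
  # numerical round-off can leave values epsilon outside [0, 1]
  seg_map(pmin(pmax(y, 0), 1), acc$spacing, acc$origin)
}

#' Keep the largest connected component of a binary map
#'
#' @param mask binary [seg_map()].
#' @param connectivity 26 (default) or 6.
#' @return binary [seg_map()] containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  lab <- cpp_label_components(array(as.numeric(mask$data > 0.5), dim(mask$data)),
                              dim(mask$data), as.integer(connectivity))
  if (max(lab) == 0L)
    vt_stop("empty mask: no connected component", "vt_empty_segmentation")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  seg_map(array(as.numeric(lab == keep), dim(mask$data)),
          mask$spacing, mask$origin, binary = TRUE)
}

#' Finalize the global assembly
#'
#' Computes the fused probability map, optionally upsamples it back to an
#' original reference grid, thresholds it (values `>= t` kept), retains the
#' largest connected body, extracts the global surface, and smooths the
#' surface with the windowed-sinc family filter (10 iterations, passband
#' 0.01 by default).
#'
#' @param acc a [global_accumulator()].
#' @param original_grid optional [image_volume()]: if supplied, the fused
#'   map is resampled onto its spacing before thresholding (the tracer may
#'   run on a resampled grid while outputs are wanted at native resolution).
#' @return list with `probability` ([seg_map()]), `binary` ([seg_map()]) and
#'   `mesh` (`surface_mesh`).
#' @export
finalize_assembly <- function(acc, original_grid = NULL) {
  cfg <- acc$cfg
  prob <- fused_map(acc)
  if (!is.null(original_grid))
    prob <- resample_volume(prob, original_grid$spacing, kind = "image")
  if (!any(prob$data >= cfg$threshold))
    vt_stop(sprintf("no voxel reaches the fusion threshold %.2f (max fused value %.3f)",
                    cfg$threshold, max(prob$data)),
            "vt_empty_segmentation")
  bin <- seg_map(array(as.numeric(prob$data >= cfg$threshold), dim(prob$data)),
                 prob$spacing, prob$origin, binary = TRUE)
  bin <- largest_component(bin, cfg$connectivity)
  mesh <- extract_surface(bin, iso = 0.5)
  mesh <- smooth_mesh(mesh, iterations = cfg$smooth_iterations,
                      passband = cfg$passband)
  list(probability = prob, binary = bin, mesh = mesh)
}

#' Windowed-sinc family mesh smoothing
#'
#' Taubin lambda/mu smoothing, the standard two-step low-pass member of the
#' windowed-sinc filter family: alternating shrink (`lambda`) and inflate
#' (`mu`) Laplacian steps whose magnitudes satisfy the passband relation
#' `k_pb = 1/lambda + 1/mu`, which removes voxelization ripple without the
#' shrinkage of plain Laplacian smoothing. Vertex count and connectivity are
#' preserved; boundary (cut-plane) vertices are kept fixed.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations number of lambda+mu passes.
#' @param passband passband frequency `k_pb` in (0, 2).
#' @param lambda positive smoothing factor in (0, 1).
#' @return the smoothed `surface_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations = 10L, passband = 0.01, lambda = 0.5) {
  mu <- 1 / (passband - 1 / lambda)
  V <- mesh$vertices
  Tr <- mesh$triangles
  n <- nrow(V)
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  e <- unique(e)
  deg <- tabulate(e[, 1], nbins = n)
  fixed <- mesh$cut_plane
  laplacian_step <- function(V, f) {
    nb_sum <- rowsum(V[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
    idx <- as.integer(rownames(nb_sum))
    L <- matrix(0, n, 3)
    L[idx, ] <- nb_sum / pmax(deg[idx], 1L) - V[idx, , drop = FALSE]
    L[fixed | deg == 0L, ] <- 0
    V + f * L
  }
  for (i in seq_len(iterations)) {
    V <- laplacian_step(V, lambda)
    V <- laplacian_step(V, mu)
  }
  mesh$vertices <- V
  mesh
}

#' Discrete curvature energy of a mesh
#'
#' Sum of squared umbrella-Laplacian magnitudes over interior vertices; a
#' simple roughness measure used to verify that smoothing reduces
#' voxelization ripple.
#'
#' @param mesh a `surface_mesh`.
#' @return nonnegative scalar.
#' @export
mesh_curvature_energy <- function(mesh) {
  V <- mesh$vertices
  Tr <- mesh$triangles
  n <- nrow(V)
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  e <- unique(rbind(e, e[, c(2, 1)]))
  deg <- tabulate(e[, 1], nbins = n)
  nb_sum <- rowsum(V[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
  idx <- as.integer(rownames(nb_sum))
  L <- matrix(0, n, 3)
  L[idx, ] <- nb_sum / pmax(deg[idx], 1L) - V[idx, , drop = FALSE]
  interior <- !mesh$cut_plane & deg > 0L
  sum(rowSums(L[interior, , drop = FALSE]^2))
}
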