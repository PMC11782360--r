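#' Extract an iso-surface mesh from a probability map
#'
#' Runs iso-surface extraction (marching over a tetrahedral decomposition of
#' each grid cell, with linear interpolation along edges) at the given iso
#' level, in physical coordinates. Where the vessel meets the boundary of the
#' subvolume the surface is left open; vertices lying on the subvolume
#' boundary planes are flagged as cut-plane vertices, from which the
#' truncation boundaries ("caps") are recovered by [find_caps()].
#'
#' @param prob_map a [seg_map()] (probabilities or binary).
#' @param iso iso level, default 0.5.
#' @return a `surface_mesh`: list with `vertices` (n-by-3 mm), `triangles`
#'   (m-by-3, 1-based), `cut_plane` (logical per vertex) and a `bounds`
#'   attribute (2-by-3 voxel-center bounding box).
#' @export
extract_surface <- function(prob_map, iso = 0.5) {
  vt_validate(inherits(prob_map, "image_volume"), "`prob_map` must be a volume")
  if (!any(prob_map$data >= iso))
    vt_stop("no voxel reaches the iso level: empty segmentation",
            "vt_empty_segmentation")
  res <- cpp_isosurface(prob_map$data, dim(prob_map$data),
                        prob_map$spacing, prob_map$origin, iso)
  V <- res$vertices; Tr <- res$triangles
  if (nrow(Tr) > 0) {
    # drop degenerate (zero-area) triangles, e.g. from values exactly at iso
    a <- V[Tr[, 2], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
    b <- V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
    cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
    cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
    cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    area2 <- sqrt(cx^2 + cy^2 + cz^2)
    Tr <- Tr[area2 > 1e-12, , drop = FALSE]
  }
  if (nrow(Tr) == 0)
    vt_stop("segmentation too thin to carry a surface", "vt_empty_segmentation")
  d <- dim(prob_map$data)
  lo <- prob_map$origin
  hi <- prob_map$origin + (d - 1) * prob_map$spacing
  tol <- min(prob_map$spacing) * 1e-6
  cut <- rep(FALSE, nrow(V))
  for (a in 1:3)
    cut <- cut | abs(V[, a] - lo[a]) < tol | abs(V[, a] - hi[a]) < tol
  structure(list(vertices = V, triangles = Tr, cut_plane = cut),
            bounds = rbind(lo, hi),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, %d cut-plane vertices\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$cut_plane)))
  invisible(x)
}

#' Total triangle area of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; Tr <- mesh$triangles
  a <- V[Tr[, 2], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# Edges used by exactly one triangle (the open boundary of the mesh).
boundary_edges <- function(mesh) {
  Tr <- mesh$triangles
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_keys <- names(cnt)[cnt == 1L]
  e[key %in% open_keys, , drop = FALSE]
}

#' Find truncation boundaries (caps) of a cut surface
#'
#' Collects the open boundary edges of the mesh, groups them into connected
#' loops, assigns each loop to the subvolume face its vertices lie on, and
#' returns one truncation boundary per loop with its center (the mean of the
#' loop vertices). If the surface is closed (no caps), a no-outlet condition
#' is signalled — in the tracer this feeds the "chances" mechanism.
#'
#' @param mesh a `surface_mesh` from [extract_surface()].
#' @return list of `truncation_boundary` objects: `center` (mm), `face`
#'   (1..6: -x, +x, -y, +y, -z, +z), `vertex_ids`, `role` (`NA` until
#'   [assign_source_target()]).
#' @export
find_caps <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0)
    vt_stop("surface is closed: no truncation boundaries", "vt_no_outlet")
  # union-find over boundary vertices
  verts <- sort(unique(as.vector(be)))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) {
      parent[[as.character(x)]] <<- parent[[as.character(parent[[as.character(x)]])]]
      x <- parent[[as.character(x)]]
    }
    x
  }
  for (i in seq_len(nrow(be))) {
    ra <- find(be[i, 1]); rb <- find(be[i, 2])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(verts, find, numeric(1))
  groups <- split(verts, roots)
  bounds <- attr(mesh, "bounds")
  caps <- lapply(groups, function(g) {
    pts <- mesh$vertices[g, , drop = FALSE]
    ctr <- colMeans(pts)
    # face: the plane all loop vertices are closest to
    dists <- c(abs(ctr[1] - bounds[1, 1]), abs(ctr[1] - bounds[2, 1]),
               abs(ctr[2] - bounds[1, 2]), abs(ctr[2] - bounds[2, 2]),
               abs(ctr[3] - bounds[1, 3]), abs(ctr[3] - bounds[2, 3]))
    structure(list(center = ctr, face = which.min(dists),
                   vertex_ids = g, role = NA_character_),
              class = "truncation_boundary")
  })
  names(caps) <- NULL
  # deterministic order: by face, then lexicographic center
  ord <- order(vapply(caps, function(cp) cp$face, numeric(1)),
               vapply(caps, function(cp) cp$center[1], numeric(1)),
               vapply(caps, function(cp) cp$center[2], numeric(1)),
               vapply(caps, function(cp) cp$center[3], numeric(1)))
  caps[ord]
}

#' Classify caps into one source and the rest targets
#'
#' The cap whose center is closest to the previous stepping point becomes the
#' source (inlet); all others become targets (outlets). Exact distance ties
#' break deterministically by lowest face id, then lexicographic center
#' (which is the order [find_caps()] already returns).
#'
#' @param caps list of `truncation_boundary` from [find_caps()].
#' @param previous_point length-3 mm point (the seed at initialization).
#' @return the caps list with `role` filled in, source first.
#' @export
assign_source_target <- function(caps, previous_point) {
  vt_validate(length(caps) >= 1L, "need at least one cap")
  d <- vapply(caps, function(cp) sqrt(sum((cp$center - previous_point)^2)),
              numeric(1))
  src <- which.min(d) # ties: first in face/lexicographic order
  for (i in seq_along(caps))
    caps[[i]]$role <- if (i == src) "source" else "target"
  caps[c(src, setdiff(seq_along(caps), src))]
}

#' Wave-propagation speed field from a binary vessel mask
#'
#' The speed is the Euclidean distance (mm) to the vessel boundary plus a
#' small epsilon inside the mask, and exactly zero outside: waves travel
#' fastest along the vessel center, which is what makes gradient descent on
#' the arrival time trace centered paths.
#'
#' @param mask binary [seg_map()].
#' @param eps floor added inside the mask so boundary voxels remain passable.
#' @return an [image_volume()] speed field.
#' @export
build_speed <- function(mask, eps = 1e-3) {
  vt_validate(inherits(mask, "image_volume"), "`mask` must be a volume")
  if (!any(mask$data > 0.5))
    vt_stop("empty mask: no speed field", "vt_empty_segmentation")
  m <- array(as.numeric(mask$data > 0.5), dim = dim(mask$data))
  dt <- cpp_edt(m, dim(m), mask$spacing)
  F <- ifelse(m > 0, dt + eps, 0)
  image_volume(array(F, dim = dim(m)), mask$spacing, mask$origin)
}

# Nearest voxel (1-based index triple) with positive speed to a mm point.
nearest_mask_voxel <- function(F, point_mm) {
  idx <- round(world_to_voxel(F, point_mm))
  d <- dim(F$data)
  idx <- pmin(pmax(idx, 1), d)
  if (F$data[idx[1], idx[2], idx[3]] > 0) return(as.integer(idx))
  w <- which(F$data > 0)
  if (length(w) == 0L) return(NULL)
  ai <- arrayInd(w, d)
  pts <- voxel_to_world(F, ai)
  j <- which.min(rowSums(sweep(pts, 2, as.numeric(point_mm))^2))
  as.integer(ai[j, ])
}

#' Solve the eikonal equation on a speed field
#'
#' Solves `|grad T| F = 1` with `T = 0` at the source by first-order fast
#' marching restricted to the domain `F > 0`. The source point is projected
#' to the nearest in-mask voxel (cap centers can fall marginally outside the
#' voxelized mask).
#'
#' @param F speed field from [build_speed()].
#' @param source length-3 mm source point.
#' @return an `eikonal_field`: list with `T` (plain array on the grid of `F`;
#'   `Inf` on unreached voxels), the speed `F`, `source` (mm, as given) and
#'   `source_voxel` (projected index).
#' @export
solve_eikonal <- function(F, source) {
  sv <- nearest_mask_voxel(F, source)
  if (is.null(sv))
    vt_stop("source point outside the mask", "vt_validation_error")
  src_lin <- sv[1] + dim(F$data)[1] * ((sv[2] - 1) + dim(F$data)[2] * (sv[3] - 1))
  T <- cpp_fast_march(F$data, dim(F$data), F$spacing, as.integer(src_lin))
  structure(list(T = T, F = F, source = as.numeric(source), source_voxel = sv),
            class = "eikonal_field")
}

#' Trace centerlines by gradient descent on the arrival-time field
#'
#' From each target cap center, descends the arrival time `T` with
#' sub-voxel steps (trilinearly interpolated central-difference gradient)
#' until within one voxel of the source, yielding one centered polyline per
#' reachable target. Per-point radii are read off the speed field (the
#' distance transform). A target on an unreached voxel signals an
#' unreachable-target condition; a descent that stops making progress before
#' reaching the source signals a stall.
#'
#' @param field an `eikonal_field` from [solve_eikonal()].
#' @param targets k-by-3 matrix (or length-3 vector) of target cap centers, mm.
#' @param step_fraction descent step as a fraction of the minimum spacing.
#' @param max_iter maximum descent iterations per target (default scales with
#'   the grid diagonal).
#' Individual targets that fail (unreachable or stalled) are dropped from
#' the result with a warning-free record in the `failed` attribute; the
#' corresponding condition is signalled only when *every* target fails.
#'
#' @return a [centerline_tree()] with one branch per surviving target,
#'   points ordered source to target; attribute `failed` lists per-target
#'   failure classes (`NA` for successes).
#' @export
trace_centerline <- function(field, targets, step_fraction = 0.25,
                             max_iter = NULL) {
  if (!is.matrix(targets)) targets <- matrix(targets, ncol = 3)
  Tarr <- field$T
  d <- dim(Tarr)
  h <- field$F$spacing
  step <- step_fraction * min(h)
  if (is.null(max_iter))
    max_iter <- ceiling(10 * sqrt(sum((d * h)^2)) / step)
  # finite surrogate outside the reached set keeps interpolation usable and
  # pushes the descent back into the mask
  finiteT <- Tarr[is.finite(Tarr)]
  bigT <- if (length(finiteT)) max(finiteT) * 2 + 10 * max(h) else 0
  Tfin <- image_volume(array(ifelse(is.finite(Tarr), Tarr, bigT), dim = d),
                       field$F$spacing, field$F$origin)
  source_mm <- voxel_to_world(Tfin, field$source_voxel)
  tol <- min(h)

  descend_one <- function(target) {
    tv <- nearest_mask_voxel(field$F, target)
    if (is.null(tv) || !is.finite(Tarr[tv[1], tv[2], tv[3]]))
      vt_stop("target cap is not reachable from the source in the mask",
              "vt_unreachable_target")
    p <- voxel_to_world(Tfin, tv)
    path <- list(p)
    reached <- sqrt(sum((p - source_mm)^2)) <= tol
    it <- 0L
    Tcur <- interp_trilinear(Tfin, p)
    while (!reached) {
      it <- it + 1L
      if (it > max_iter)
        vt_stop("centerline descent stalled before reaching the source",
                "vt_stall_error")
      g <- interp_gradient(Tfin, p)
      ng <- sqrt(sum(g^2))
      moved <- FALSE
      if (is.finite(ng) && ng > 1e-12) {
        pn <- p - step * g / ng
        Tn <- interp_trilinear(Tfin, pn)
        if (Tn < Tcur) { p <- pn; Tcur <- Tn; moved <- TRUE }
      }
      if (!moved) {
        # sub-voxel step made no progress (thin channels, plateaus): fall
        # back to discrete steepest descent on the voxel lattice, which
        # strictly decreases T until the source voxel
        cv <- pmin(pmax(round(world_to_voxel(Tfin, p)), 1), d)
        nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
        nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
        cand <- sweep(nb, 2, cv, "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
        cand <- cand[ok, , drop = FALSE]
        tv_vals <- Tarr[cand]
        tv_here <- Tarr[matrix(cv, 1)]
        if (!any(is.finite(tv_vals)) ||
            min(tv_vals, na.rm = TRUE) >= tv_here)
          vt_stop("centerline descent stalled on a plateau", "vt_stall_error")
        cv <- cand[which.min(tv_vals), ]
        p <- voxel_to_world(Tfin, cv)
        Tcur <- Tarr[matrix(cv, 1)]
      }
      path[[length(path) + 1L]] <- p
      reached <- sqrt(sum((p - source_mm)^2)) <= tol
    }
    pts <- do.call(rbind, rev(path)) # source -> target
    pts <- rbind(source_mm, pts)
    # distance-transform values measure to the nearest background voxel
    # center; the iso-surface lies about half a voxel closer
    rad <- pmax(interp_trilinear(field$F, pts) - min(h) / 2, 1e-6)
    list(points = pts, radius = rad)
  }

  branches <- list()
  reached_targets <- list()
  failed <- rep(NA_character_, nrow(targets))
  last_cond <- NULL
  for (k in seq_len(nrow(targets))) {
    br <- tryCatch(descend_one(targets[k, ]), vt_error = function(e) e)
    if (inherits(br, "vt_error")) {
      failed[k] <- setdiff(class(br), c("vt_error", "error", "condition"))[1]
      last_cond <- br
    } else {
      branches[[length(branches) + 1L]] <- br
      reached_targets[[length(reached_targets) + 1L]] <- targets[k, ]
    }
  }
  if (length(branches) == 0L) stop(last_cond)
  tree <- centerline_tree(branches, source = source_mm,
                          target_points = do.call(rbind, reached_targets))
  attr(tree, "failed") <- failed
  tree
}

# Central-difference gradient of a volume at a mm point, via trilinear
# interpolation at +/- half a voxel.
interp_gradient <- function(vol, p) {
  h <- vol$spacing / 2
  pts <- rbind(p + c(h[1], 0, 0), p - c(h[1], 0, 0),
               p + c(0, h[2], 0), p - c(0, h[2], 0),
               p + c(0, 0, h[3]), p - c(0, 0, h[3]))
  v <- interp_trilinear(vol, pts)
  c((v[1] - v[2]) / (2 * h[1]), (v[3] - v[4]) / (2 * h[2]),
    (v[5] - v[6]) / (2 * h[3]))
}

#' Estimate per-point radii along a centerline
#'
#' The radius at each centerline point is its distance to the vessel wall:
#' by default the (interpolated) Euclidean distance transform of the binary
#' mask; alternatively the distance to the nearest surface-mesh vertex.
#'
#' @param tree a [centerline_tree()].
#' @param mask binary [seg_map()] (used when `method = "mask"`).
#' @param mesh a `surface_mesh` (used when `method = "surface"`).
#' @param method `"mask"` (distance transform, default) or `"surface"`.
#' @return the tree with `radius` replaced by the estimates.
#' @export
estimate_radius <- function(tree, mask = NULL, mesh = NULL,
                            method = c("mask", "surface")) {
  method <- match.arg(method)
  if (method == "mask") {
    vt_validate(!is.null(mask), "`mask` is required for method = \"mask\"")
    F <- build_speed(mask, eps = 0)
    half <- min(mask$spacing) / 2
    tree$branches <- lapply(tree$branches, function(b) {
      b$radius <- pmax(interp_trilinear(F, b$points) - half, 1e-6)
      b
    })
  } else {
    vt_validate(!is.null(mesh), "`mesh` is required for method = \"surface\"")
    V <- mesh$vertices
    tree$branches <- lapply(tree$branches, function(b) {
      b$radius <- pmax(vapply(seq_len(nrow(b$points)), function(i)
        sqrt(min(rowSums(sweep(V, 2, b$points[i, ])^2))), numeric(1)), 1e-6)
      b
    })
  }
  tree
}
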