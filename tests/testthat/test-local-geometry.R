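test_that("iso-surface of a ball has near-analytic area", {
  n <- 21; r <- 5
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  dist <- sqrt(rowSums(sweep(g, 2, rep(11, 3))^2))
  # one-voxel anti-aliased ball: sub-voxel iso placement
  aa <- seg_map(array(pmin(pmax(0.5 + (r - dist), 0), 1), rep(n, 3)))
  expect_lt(abs(mesh_area(extract_surface(aa)) / (4 * pi * r^2) - 1), 0.10)
  # a hard binary ball carries staircase area, removed by the standard
  # smoothing schedule the pipeline applies
  hard <- extract_surface(make_ball(r = r, n = n))
  smoothed <- smooth_mesh(hard, iterations = 10, passband = 0.01)
  expect_lt(abs(mesh_area(smoothed) / (4 * pi * r^2) - 1), 0.10)
})

test_that("empty probability maps refuse to produce a surface", {
  expect_error(extract_surface(seg_map(array(0, c(5, 5, 5)))),
               class = "vt_empty_segmentation")
})

test_that("caps: cylinder has two, a closed ball none, a junction three", {
  n <- 15
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  cyl <- seg_map(array(as.numeric((g[, 1] - 8)^2 + (g[, 2] - 8)^2 <= 16),
                       rep(n, 3)))
  caps <- find_caps(extract_surface(cyl))
  expect_length(caps, 2L)
  expect_setequal(vapply(caps, function(cp) cp$face, numeric(1)), c(5, 6))
  # cap centers sit on the tube axis at the two z faces
  for (cp in caps) expect_lt(max(abs(cp$center[1:2] - 7)), 1)
  expect_error(find_caps(extract_surface(make_ball(4, 13))),
               class = "vt_no_outlet")
  # Y-junction subvolume: three truncation boundaries
  ph <- std_suite$y_bifurcation
  sub <- extract_subvolume(ph$truth_mask, subvolume_spec(c(18, 0, 0), 12))
  ycaps <- find_caps(extract_surface(seg_map(sub$data, sub$spacing, sub$origin)))
  expect_length(ycaps, 3L)
})

test_that("source/target assignment picks the cap nearest the previous point", {
  mkcap <- function(ctr, face) structure(list(center = ctr, face = face,
                                              vertex_ids = 1L, role = NA),
                                         class = "truncation_boundary")
  caps <- list(mkcap(c(1, 0, 0), 1), mkcap(c(5, 0, 0), 2))
  out <- assign_source_target(caps, c(0, 0, 0))
  expect_equal(out[[1]]$role, "source")
  expect_equal(out[[1]]$center, c(1, 0, 0))
  expect_equal(out[[2]]$role, "target")
  # single cap: it is the source, zero targets
  one <- assign_source_target(caps[1], c(0, 0, 0))
  expect_equal(one[[1]]$role, "source")
  # exact tie: lowest face id wins, stable across calls
  tie <- list(mkcap(c(0, 0, 1), 5), mkcap(c(0, 0, -1), 6))
  r1 <- assign_source_target(tie, c(0, 0, 0))
  r2 <- assign_source_target(tie, c(0, 0, 0))
  expect_equal(r1[[1]]$face, 5)
  expect_identical(vapply(r1, function(cp) cp$face, numeric(1)),
                   vapply(r2, function(cp) cp$face, numeric(1)))
})

test_that("speed fields are distance transforms inside, zero outside", {
  mask <- extract_subvolume(clean_tube$truth_mask, subvolume_spec(c(15, 0, 0), 14))
  mask <- seg_map(mask$data, mask$spacing, mask$origin, binary = TRUE)
  F <- build_speed(mask, eps = 1e-3)
  expect_true(all(F$data[mask$data == 0] == 0))
  axis_val <- interp_trilinear(F, c(15, 0, 0))
  expect_lt(abs(axis_val - 3), 0.6) # ~ tube radius at the centerline
  # boundary voxels carry ~ one-voxel distances
  inside <- which(mask$data == 1)
  expect_gt(min(F$data[inside]), 0)
  expect_lt(min(F$data[inside]), 2 * max(mask$spacing))
  expect_error(build_speed(seg_map(array(0, c(4, 4, 4)))),
               class = "vt_empty_segmentation")
})

test_that("constant-speed arrival times equal Euclidean distance", {
  d <- c(21, 21, 21)
  f <- solve_eikonal(image_volume(array(1, d)), c(10, 10, 10))
  g <- as.matrix(expand.grid(0:20, 0:20, 0:20))
  tru <- sqrt(rowSums(sweep(g, 2, rep(10, 3))^2))
  expect_lt(max(abs(as.vector(f$T) - tru)), 1) # <= 1 voxel over a 20-voxel grid
})

test_that("arrival times are causal (monotone along the propagation order)", {
  set.seed(8)
  mk <- random_blob(15)
  F <- build_speed(mk)
  w <- which(mk$data > 0.5)
  f <- solve_eikonal(F, voxel_to_world(F, arrayInd(w[1], dim(F$data))))
  Tv <- f$T
  d <- dim(Tv)
  fin <- which(is.finite(Tv) & Tv > 0)
  ai <- arrayInd(fin, d)
  for (ax in 1:3) {
    for (dir in c(-1, 1)) {
      nbi <- ai; nbi[, ax] <- nbi[, ax] + dir
      ok <- nbi[, ax] >= 1 & nbi[, ax] <= d[ax]
      tn <- Tv[nbi[ok, , drop = FALSE]]
      # every voxel's T exceeds the smallest neighbouring T
      expect_true(all(Tv[ai[ok, , drop = FALSE]] >
                        pmin(tn, Tv[ai[ok, , drop = FALSE]]) - 1e-9))
    }
  }
  # source outside the domain errors
  empty_src <- tryCatch(solve_eikonal(F, c(1e3, 1e3, 1e3)), error = function(e) e)
  expect_true(is.list(empty_src)) # projected to nearest in-mask voxel, no error
})

test_that("centerlines stay on the axis of a straight tube", {
  sub <- extract_subvolume(clean_tube$truth_mask, subvolume_spec(c(15, 0, 0), 14))
  mask <- seg_map(sub$data, sub$spacing, sub$origin, binary = TRUE)
  F <- build_speed(mask)
  caps <- find_caps(extract_surface(mask))
  caps <- assign_source_target(caps, c(5, 0, 0))
  f <- solve_eikonal(F, caps[[1]]$center)
  tree <- trace_centerline(f, caps[[2]]$center)
  pts <- tree$branches[[1]]$points
  dev <- sqrt(pts[, 2]^2 + pts[, 3]^2)
  expect_lt(max(dev), min(mask$spacing)) # within one voxel of the true axis
  # radius estimates along the mid-branch
  mid <- pts[, 1] > 10 & pts[, 1] < 20
  expect_lt(max(abs(tree$branches[[1]]$radius[mid] - 3)),
            0.5 * max(mask$spacing) + 0.26)
})

test_that("Y-junction centerlines share their proximal course", {
  ph <- std_suite$y_bifurcation
  sub <- extract_subvolume(ph$truth_mask, subvolume_spec(c(18, 0, 0), 14))
  mask <- seg_map(sub$data, sub$spacing, sub$origin, binary = TRUE)
  caps <- find_caps(extract_surface(mask))
  caps <- assign_source_target(caps, c(10, 0, 0))
  f <- solve_eikonal(F <- build_speed(mask), caps[[1]]$center)
  targets <- do.call(rbind, lapply(caps[-1], function(cp) cp$center))
  tree <- trace_centerline(f, targets)
  expect_length(tree$branches, 2L)
  # both branches descend to the same source: proximal ends within 2 voxels
  p1 <- tree$branches[[1]]$points[1, ]
  p2 <- tree$branches[[2]]$points[1, ]
  expect_lt(sqrt(sum((p1 - p2)^2)), 2 * min(mask$spacing))
})

test_that("radius estimation follows the mask distance transform", {
  tree <- clean_tube$truth_centerline
  est <- estimate_radius(tree, mask = clean_tube$truth_mask)
  mid <- est$branches[[1]]$points[, 1] > 5 & est$branches[[1]]$points[, 1] < 25
  expect_lt(max(abs(est$branches[[1]]$radius[mid] - 3)),
            0.5 * max(clean_tube$truth_mask$spacing))
  # a point on the surface has near-zero radius
  surf_tree <- centerline_tree(list(list(points = matrix(c(15, 3, 0), 1),
                                         radius = 1)))
  est2 <- estimate_radius(surf_tree, mask = clean_tube$truth_mask)
  expect_lt(est2$branches[[1]]$radius, 0.75)
  # tapering tube: radii nonincreasing downstream after 3-point smoothing
  taper <- std_suite$tapering
  tt <- centerline_tree(list(list(
    points = do.call(rbind, lapply(taper$truth_centerline$branches,
                                   function(b) b$points)),
    radius = unlist(lapply(taper$truth_centerline$branches,
                           function(b) b$radius)))))
  et <- estimate_radius(tt, mask = taper$truth_mask)
  r <- et$branches[[1]]$radius
  sm <- stats::filter(r, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= max(taper$truth_mask$spacing) / 2))
})
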