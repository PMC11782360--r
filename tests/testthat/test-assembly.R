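test_that("the fusion weight kernel has the documented profile", {
  L <- 12
  expect_equal(fusion_weight(0, L), 1)
  # face center: two standard deviations from the cube center
  expect_equal(fusion_weight(L / 2, L), exp(-4))
  expect_equal(round(fusion_weight(2 * (L / 4), L), 2), 0.02)
  expect_equal(fusion_weight(L / 4, L), exp(-1))
  # the weight map agrees with the scalar kernel at the center voxel
  patch <- image_volume(array(0, c(11, 11, 11)), spacing = rep(1, 3),
                        origin = c(-5, -5, -5))
  w <- weight_map(patch, subvolume_spec(c(0, 0, 0), 10))
  expect_equal(w[6, 6, 6], 1)
  expect_true(all(w > 0 & w <= 1))
})

test_that("overlapping constant predictions fuse to the same constant", {
  ref <- image_volume(array(0, c(30, 30, 30)), spacing = rep(1, 3))
  acc <- global_accumulator(ref)
  set.seed(21)
  for (i in 1:6) {
    ctr <- runif(3, 8, 22)
    side <- runif(1, 5, 10)
    spec <- subvolume_spec(ctr, side)
    sub <- extract_subvolume(ref, spec)
    pred <- seg_map(array(0.7, dim(sub$data)), sub$spacing, sub$origin)
    acc <- accumulate(acc, pred, spec)
  }
  fused <- fused_map(acc)
  covered <- acc$w > 0
  expect_true(any(covered))
  expect_equal(range(fused$data[covered]), c(0.7, 0.7), tolerance = 1e-12)
  expect_true(all(fused$data[!covered] == 0))
})

test_that("a single cube fuses to its own prediction; equal weights average", {
  ref <- image_volume(array(0, c(20, 20, 20)), spacing = rep(1, 3))
  acc <- global_accumulator(ref)
  spec <- subvolume_spec(c(10, 10, 10), 8)
  sub <- extract_subvolume(ref, spec)
  set.seed(4)
  pred <- seg_map(array(runif(prod(dim(sub$data))), dim(sub$data)),
                  sub$spacing, sub$origin)
  acc <- accumulate(acc, pred, spec)
  fused <- fused_map(acc)
  ir <- attr(sub, "index_range")
  expect_equal(fused$data[ir[1, 1]:ir[2, 1], ir[1, 2]:ir[2, 2], ir[1, 3]:ir[2, 3]],
               pred$data, tolerance = 1e-12)
  # two cubes, symmetric about a voxel, predicting 1 and 0 -> fused 0.5
  acc2 <- global_accumulator(ref)
  sA <- subvolume_spec(c(8, 10, 10), 8); sB <- subvolume_spec(c(12, 10, 10), 8)
  subA <- extract_subvolume(ref, sA); subB <- extract_subvolume(ref, sB)
  acc2 <- accumulate(acc2, seg_map(array(1, dim(subA$data)), subA$spacing, subA$origin), sA)
  acc2 <- accumulate(acc2, seg_map(array(0, dim(subB$data)), subB$spacing, subB$origin), sB)
  f2 <- fused_map(acc2)
  # voxel at (10, 10, 10) is equidistant from both centers
  expect_equal(f2$data[11, 11, 11], 0.5, tolerance = 1e-12)
  expect_equal(max(acc2$visits), 2L)
})

test_that("fused values stay in [0, 1] and thresholding is monotone", {
  ref <- image_volume(array(0, c(25, 25, 25)), spacing = rep(1, 3))
  acc <- global_accumulator(ref)
  set.seed(31)
  for (i in 1:8) {
    spec <- subvolume_spec(runif(3, 8, 17), runif(1, 4, 9))
    sub <- extract_subvolume(ref, spec)
    pred <- seg_map(array(runif(prod(dim(sub$data))), dim(sub$data)),
                    sub$spacing, sub$origin)
    acc <- accumulate(acc, pred, spec)
  }
  fused <- fused_map(acc)
  expect_gte(min(fused$data), 0)
  expect_lte(max(fused$data), 1)
  counts <- vapply(seq(0.1, 0.9, by = 0.1),
                   function(t) sum(fused$data >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("finalize keeps the largest body and a voxel exactly at threshold", {
  arr <- array(0, c(30, 12, 12))
  arr[2:11, 3:8, 3:8] <- 1     # 360 voxels
  arr[20:22, 5:7, 5:7] <- 1    # 27 voxels, disjoint
  m <- seg_map(arr, spacing = rep(1, 3))
  keep <- largest_component(m)
  expect_equal(sum(keep$data), 360)
  expect_equal(sum(keep$data[20:22, , ]), 0)
  # fused value exactly at the threshold is kept (>=)
  ref <- image_volume(array(0, c(16, 16, 16)), spacing = rep(1, 3))
  acc <- global_accumulator(ref)
  spec <- subvolume_spec(c(8, 8, 8), 8)
  sub <- extract_subvolume(ref, spec)
  acc <- accumulate(acc, seg_map(array(0.5, dim(sub$data)), sub$spacing, sub$origin), spec)
  fin <- finalize_assembly(acc)
  expect_equal(sum(fin$binary$data), prod(dim(sub$data)))
  expect_s3_class(fin$mesh, "surface_mesh")
  # an accumulator below threshold errors with diagnostics
  acc0 <- global_accumulator(ref)
  acc0 <- accumulate(acc0, seg_map(array(0.2, dim(sub$data)), sub$spacing, sub$origin), spec)
  expect_error(finalize_assembly(acc0), class = "vt_empty_segmentation")
})

test_that("windowed-sinc family smoothing preserves vertices, reduces roughness", {
  mesh <- extract_surface(make_ball(5, 21))
  sm <- smooth_mesh(mesh, iterations = 10, passband = 0.01)
  expect_equal(nrow(sm$vertices), nrow(mesh$vertices))
  expect_identical(sm$triangles, mesh$triangles)
  expect_lt(mesh_curvature_energy(sm), mesh_curvature_energy(mesh))
})
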