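test_that("NIfTI and MetaImage round trips preserve data, spacing and origin", {
  vol <- image_volume(array(rnorm(8 * 7 * 6), c(8, 7, 6)),
                      spacing = c(1, 0.5, 0.5), origin = c(-3, 2, 7.5))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    write_volume(vol, f)
    back <- read_volume(f)
    expect_equal(back$data, vol$data, tolerance = 1e-6)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
    expect_equal(back$origin, vol$origin, tolerance = 1e-6)
    unlink(f)
    unlink(sub("\\.mhd$", ".raw", f))
  }
})

test_that("reading a missing file errors", {
  expect_error(read_volume(tempfile(fileext = ".nii.gz")),
               class = "vt_validation_error")
})

test_that("coordinate transforms round trip within half a voxel", {
  vol <- image_volume(array(0, c(10, 12, 14)), spacing = c(0.7, 1.1, 0.4),
                      origin = c(5, -2, 0))
  set.seed(1)
  pts <- cbind(runif(50, 5, 5 + 9 * 0.7), runif(50, -2, -2 + 11 * 1.1),
               runif(50, 0, 13 * 0.4))
  back <- voxel_to_world(vol, round(world_to_voxel(vol, pts)))
  expect_true(all(abs(back - pts) <= rep(vol$spacing / 2 + 1e-9, each = 50)))
  expect_equal(world_to_voxel(vol, voxel_to_world(vol, c(3, 4, 5))), c(3, 4, 5))
})

test_that("MR z-score normalization gives mean 0, sd 1", {
  vol <- image_volume(array(rnorm(20^3, 50, 7), rep(20, 3)))
  st <- fit_normalization(list(vol), mode = "mr_zscore")
  nv <- normalize_volume(vol, st)
  expect_lt(abs(mean(nv$data)), 1e-6)
  expect_lt(abs(sqrt(mean((nv$data - mean(nv$data))^2)) - 1), 1e-6)
})

test_that("constant image normalizes without error (epsilon-guarded sigma)", {
  vol <- image_volume(array(3, rep(5, 3)))
  nv <- normalize_volume(vol, fit_normalization(list(vol), mode = "mr_zscore"))
  expect_true(all(is.finite(nv$data)))
  expect_equal(unique(as.vector(nv$data)), 0)
})

test_that("CT foreground statistics pool vessel voxels and clip as configured", {
  img <- image_volume(array(0, c(4, 1, 1)))
  img$data[] <- c(10, 10, 20, 20)
  msk <- seg_map(array(1, c(4, 1, 1)), binary = TRUE)
  st <- fit_normalization(list(img), list(msk), mode = "ct_clip_foreground")
  expect_equal(st$mu, 15)
  expect_equal(st$sigma, 5) # population convention
  # percentile convention: linear interpolation between order statistics
  big <- image_volume(array(as.numeric(1:1000), c(10, 10, 10)))
  bmask <- seg_map(array(1, c(10, 10, 10)), binary = TRUE)
  st2 <- fit_normalization(list(big), list(bmask), mode = "ct_clip_foreground")
  expect_equal(st2$clip_lo, 5.995)
  expect_equal(st2$clip_hi, 995.005)
  # values above the clip bound map to the clipped transform
  probe <- image_volume(array(1e6, c(2, 2, 2)))
  np <- normalize_volume(probe, st2)
  expect_equal(unique(as.vector(np$data)), (st2$clip_hi - st2$mu) / st2$sigma)
  # empty foreground errors
  expect_error(fit_normalization(list(big),
                                 list(seg_map(array(0, c(10, 10, 10)), binary = TRUE)),
                                 mode = "ct_clip_foreground"),
               class = "vt_validation_error")
})

test_that("resampling to the same spacing is the identity", {
  vol <- image_volume(array(rnorm(10 * 11 * 12), c(10, 11, 12)),
                      spacing = c(1, 0.5, 0.5))
  out <- resample_volume(vol, c(1, 0.5, 0.5), kind = "image")
  expect_equal(out$data, vol$data, tolerance = 1e-9)
  expect_equal(out$origin, vol$origin)
})

test_that("a constant volume resamples to the same constant", {
  vol <- image_volume(array(2.5, c(9, 9, 9)), spacing = c(1, 1, 1))
  out <- resample_volume(vol, 0.4, kind = "image")
  expect_equal(range(out$data), c(2.5, 2.5), tolerance = 1e-9)
})

test_that("label resampling stays binary and preserves the interface location", {
  # half-0 / half-1 volume split at the plane x = 10.5 (between voxels 10, 11)
  arr <- array(0, c(20, 8, 8)); arr[11:20, , ] <- 1
  lab <- seg_map(arr, spacing = c(1, 1, 1))
  for (target in c(0.5, 2)) {
    out <- resample_volume(lab, target, kind = "label")
    expect_true(all(out$data %in% c(0, 1)))
    xcoords <- out$origin[1] + (seq_len(dim(out$data)[1]) - 1) * out$spacing[1]
    iface <- min(xcoords[apply(out$data, 1, max) == 1])
    # interface (at physical x = 10, first foreground voxel center) within one
    # target voxel of the truth
    expect_lt(abs(iface - 10), target + 1e-9)
  }
  # a ball mask down/up-sampled stays binary
  ball <- make_ball(r = 4, n = 15)
  expect_true(all(resample_volume(ball, 0.7, "label")$data %in% c(0, 1)))
  expect_true(all(resample_volume(ball, 1.6, "label")$data %in% c(0, 1)))
})

test_that("subvolume extraction crops the right cube and flags protrusion", {
  vol <- image_volume(array(rnorm(40^3), rep(40, 3)), spacing = rep(0.5, 3))
  sub <- extract_subvolume(vol, subvolume_spec(c(10, 10, 10), 5))
  expect_equal(dim(sub$data), rep(10, 3), tolerance = 1) # ~ L / spacing per axis
  # crop preserves the physical frame: same values at the same physical point
  p <- c(10.25, 9.75, 10.25)
  expect_equal(interp_trilinear(sub, p), interp_trilinear(vol, p))
  ir <- attr(sub, "index_range")
  expect_equal(sub$origin, voxel_to_world(vol, ir[1, ]))
  # a cube centered on a corner is out of bounds
  expect_error(extract_subvolume(vol, subvolume_spec(c(0, 0, 0), 5)),
               class = "vt_out_of_bounds")
  # entirely outside
  expect_error(extract_subvolume(vol, subvolume_spec(c(100, 100, 100), 5)),
               class = "vt_out_of_bounds")
  # partial cubes allowed up to the configured outside fraction
  sub2 <- extract_subvolume(vol, subvolume_spec(c(0.5, 10, 10), 5),
                            max_outside_fraction = 0.5)
  expect_lt(attr(sub2, "outside_fraction"), 0.5)
})
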