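test_that("oracle segmenter satisfies the segmenter contract", {
  seg <- oracle_segmenter(threshold = 0.5, smooth_sigma = 0)
  sub <- extract_subvolume(clean_tube$image, subvolume_spec(c(15, 0, 0), 12))
  p1 <- seg(sub)
  expect_s3_class(p1, "seg_map")
  expect_identical(dim(p1$data), dim(sub$data))
  expect_equal(p1$spacing, sub$spacing)
  expect_true(all(p1$data >= 0 & p1$data <= 1))
  # deterministic
  expect_identical(p1$data, seg(sub)$data)
  # two-level patch, threshold midway: probability > 0.5 exactly inside
  expect_identical(p1$data > 0.5, sub$data == 1)
  # all-background patch stays below 0.5
  bg <- image_volume(array(0, c(6, 6, 6)))
  expect_lt(max(seg(bg)$data), 0.5)
  # random input stays in range
  rnd <- image_volume(array(rnorm(5^3), c(5, 5, 5)))
  expect_true(all(seg(rnd)$data >= 0 & seg(rnd)$data <= 1))
})

test_that("segmenter registry resolves names", {
  expect_s3_class(get_segmenter("oracle"), "vt_segmenter")
  expect_s3_class(get_segmenter("oracle:0.3"), "vt_segmenter")
  expect_error(get_segmenter("cnn"), class = "vt_validation_error")
})

test_that("Dice score matches hand counts and its invariants", {
  a <- array(0, c(4, 4, 1)); a[1:2, 1:2, 1] <- 1
  b <- array(0, c(4, 4, 1)); b[2:3, 1:2, 1] <- 1 # overlap 2, |a|=|b|=4
  expect_equal(dice_score(a, b), 0.5)
  expect_equal(dice_score(a, a), 1)
  disj <- array(0, c(4, 4, 1)); disj[4, 4, 1] <- 1
  expect_equal(dice_score(a, disj), 0)
  # symmetry, empty-empty convention, soft == binary on {0,1}
  expect_equal(dice_score(a, b), dice_score(b, a))
  z <- array(0, c(3, 3, 1))
  expect_equal(dice_score(z, z), 1)
  expect_equal(dice_score(a * 1.0, b * 1.0), dice_score(a > 0, b > 0))
  expect_error(dice_score(a, array(0, c(5, 5, 1))), class = "vt_validation_error")
})

test_that("cross-entropy is the mean Bernoulli log-likelihood", {
  yt <- array(c(1, 0, 1, 0), c(4, 1, 1))
  half <- array(0.5, c(4, 1, 1))
  expect_equal(cross_entropy(half, yt), log(0.5), tolerance = 1e-12)
  # perfect prediction ~ 0 within the epsilon clamp
  expect_lt(abs(cross_entropy(yt, yt)), 1e-7 * abs(log(1e-7)) * 2)
  # single voxel closed form
  expect_equal(cross_entropy(array(0.25, c(1, 1, 1)), array(1, c(1, 1, 1))),
               log(0.25))
  expect_error(cross_entropy(half, array(1, c(2, 1, 1))),
               class = "vt_validation_error")
})

test_that("batch loss is ~0 for perfect predictions and decreases toward truth", {
  mk <- function(arr) seg_map(arr)
  yt <- array(0, c(4, 4, 4)); yt[2:3, 2:3, 2:3] <- 1
  perfect <- lapply(1:3, function(i) mk(yt))
  rep_t <- lapply(1:3, function(i) mk(yt))
  rep0 <- batch_loss(rep_t, perfect)
  expect_lt(abs(rep0$total), 1e-5)
  # half-map prediction: total = 1 - D(0.5 map, yt) + log 2
  half <- mk(array(0.5, dim(yt)))
  r1 <- batch_loss(list(mk(yt)), list(half))
  d_half <- 2 * sum(0.5 * yt) / (sum(yt) + 0.5 * length(yt))
  expect_equal(r1$total, 1 - d_half - log(0.5), tolerance = 1e-9)
  # loss decreases monotonically as the prediction is interpolated toward truth
  lam <- seq(0, 1, by = 0.1)
  losses <- vapply(lam, function(l) {
    pred <- mk((1 - l) * array(0.5, dim(yt)) + l * yt)
    batch_loss(list(mk(yt)), list(pred))$total
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(batch_loss(perfect, perfect[1:2]), class = "vt_validation_error")
})
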