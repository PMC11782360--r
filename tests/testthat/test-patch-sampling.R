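test_that("perpendicular unit vectors are unit length and orthogonal", {
  set.seed(11)
  tg <- c(0, 0, 1)
  for (i in 1:50) {
    w <- perpendicular_unit_vector(tg)
    expect_lt(abs(w[3]), 1e-9)        # zero component along the tangent
    expect_equal(sum(w^2), 1, tolerance = 1e-12)
  }
  dots <- replicate(1000, {
    t2 <- rnorm(3)
    abs(sum(perpendicular_unit_vector(t2) * t2 / sqrt(sum(t2^2))))
  })
  expect_lt(max(dots), 1e-9)
  expect_error(perpendicular_unit_vector(c(0, 0, 0)), class = "vt_validation_error")
})

test_that("in-plane direction follows the square-draw angle law", {
  # w = (a u + b v)/||.|| with a, b ~ U[-1,1]: the in-plane angle density is
  # proportional to r_max(theta)^2 = 1/max(cos, sin)^2 (corners of the square
  # load the diagonals), NOT uniform. Expected bin masses come from the
  # analytic density; the chi-square checks the sampler against them.
  set.seed(12)
  n <- 1e4
  tg <- c(0, 0, 1)
  # recover the (u, v) basis the sampler uses for this tangent
  ref <- c(1, 0, 0)
  u <- c(tg[2] * ref[3] - tg[3] * ref[2], tg[3] * ref[1] - tg[1] * ref[3],
         tg[1] * ref[2] - tg[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(tg[2] * u[3] - tg[3] * u[2], tg[3] * u[1] - tg[1] * u[3],
         tg[1] * u[2] - tg[2] * u[1])
  ang <- replicate(n, {
    w <- perpendicular_unit_vector(tg)
    atan2(sum(w * v), sum(w * u)) %% (2 * pi)
  })
  nbins <- 12L
  breaks <- seq(0, 2 * pi, length.out = nbins + 1)
  obs <- table(cut(ang, breaks, include.lowest = TRUE))
  dens <- function(th) 1 / pmax(abs(cos(th)), abs(sin(th)))^2
  p <- vapply(seq_len(nbins), function(k)
    stats::integrate(dens, breaks[k], breaks[k + 1])$value, numeric(1))
  p <- p / sum(p)
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = p))
  expect_gt(chi$p.value, 0.001)
})

test_that("degenerate variances give the deterministic five-radius cube", {
  cfg <- sampler_config(var_r = 0, var_s = 0)
  set.seed(3)
  sp <- sample_patch_spec(c(1, 2, 3), R = 2, tangent = c(1, 0, 0), cfg)
  expect_equal(sp$side, 10)
  expect_equal(sp$center, c(1, 2, 3))
})

test_that("sampled side and shift recover the configured moments", {
  cfg <- sampler_config()
  set.seed(2024)
  n <- 1e5
  R <- 2
  C <- c(0, 0, 0)
  specs <- lapply(seq_len(n), function(i)
    sample_patch_spec(C, R, c(0, 0, 1), cfg))
  alpha <- vapply(specs, function(s) s$side / R, numeric(1))
  expect_lt(abs(mean(alpha) - 5), 0.03)
  expect_lt(abs(var(alpha) - 1), 0.05)
  # signed in-plane offset beta = ||c - C|| with random sign has mean ~ 0 and
  # variance ~ var_s * R^2; the norm is |beta| * R
  off2 <- vapply(specs, function(s) sum((s$center - C)^2), numeric(1))
  expect_lt(abs(mean(off2) - 0.8 * R^2), 0.05 * R^2)
  zcomp <- vapply(specs, function(s) s$center[3], numeric(1))
  expect_lt(max(abs(zcomp)), 1e-9) # shift is perpendicular to the tangent
})

test_that("patch datasets have the expected count, content and reproducibility", {
  sp <- tree_spec(list(list(start = c(0, 0, 0), end = c(19, 0, 0), radius = 2,
                            parent = NA)),
                  blur_sigma = 0, noise_sigma = 0, spacing = 1,
                  margin_mm = 12, seed = 5L)
  ph <- make_phantom(sp)
  # exactly 20 centerline points at stride chosen to hit 1 mm steps
  cl <- ph$truth_centerline$branches[[1]]
  stride <- (nrow(cl$points) - 1) %/% 19
  cfg <- sampler_config(samples_per_point = 2L, seed = 42L)
  ds <- build_patch_dataset(ph, cfg, patch_grid_shape = c(12L, 12L, 12L),
                            point_stride = stride)
  n_points <- length(seq(1L, nrow(cl$points), by = stride))
  expect_equal(length(ds$pairs) + ds$n_skipped, 2L * n_points)
  expect_equal(ds$n_skipped, 0L) # generous margin keeps every cube inside
  for (pair in ds$pairs) {
    expect_equal(dim(pair$image_patch$data), c(12L, 12L, 12L))
    expect_true(all(pair$label_patch$data %in% c(0, 1)))
  }
  # every label patch contains vessel when the cube is centered and wide
  cfg0 <- sampler_config(var_r = 0, var_s = 0, samples_per_point = 1L, seed = 1L)
  ds0 <- build_patch_dataset(ph, cfg0, patch_grid_shape = c(12L, 12L, 12L),
                             point_stride = stride)
  frac <- vapply(ds0$pairs, function(p) mean(p$label_patch$data), numeric(1))
  expect_true(all(frac > 0))
  # bitwise reproducibility under a fixed seed
  ds2 <- build_patch_dataset(ph, cfg, patch_grid_shape = c(12L, 12L, 12L),
                             point_stride = stride)
  expect_identical(lapply(ds$pairs, function(p) p$image_patch$data),
                   lapply(ds2$pairs, function(p) p$image_patch$data))
})
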