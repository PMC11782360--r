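test_that("subvolume side length averages the two radius estimates", {
  expect_equal(next_side_length(2, 2), 10)
  expect_equal(next_side_length(1, 3), 10)
  expect_equal(next_side_length(2, 2, multiplier = 4), 8)
  expect_error(next_side_length(0, 1), class = "vt_validation_error")
})

test_that("chances advance one radius and die at the allowance", {
  adv <- take_chance(c(0, 0, 0), c(1, 0, 0), 2, chances = 0L)
  expect_equal(adv$point, c(2, 0, 0))
  expect_equal(adv$chances, 1L)
  adv2 <- take_chance(adv$point, c(0, 1, 0), 1.5, chances = adv$chances)
  expect_equal(adv2$point, c(2, 1.5, 0))
  expect_error(take_chance(c(0, 0, 0), c(1, 0, 0), 2, chances = 3L),
               class = "vt_branch_dead")
})

test_that("subvolume enlargement reacts to the predicted vessel fraction", {
  img <- clean_tube$image
  cfg <- tracer_config()
  # an all-ones segmenter keeps gamma at 1: enlarge to the budget, flagged
  ones <- as_segmenter(function(v) seg_map(array(1, dim(v$data)), v$spacing, v$origin))
  r1 <- enlarge_until_ok(ones, img, subvolume_spec(c(15, 0, 0), 4), cfg)
  expect_equal(r1$enlargements, cfg$max_enlargements)
  expect_false(r1$gamma_ok)
  expect_equal(r1$gamma, 1)
  # an all-zeros prediction never enlarges
  zeros <- as_segmenter(function(v) seg_map(array(0, dim(v$data)), v$spacing, v$origin))
  r0 <- enlarge_until_ok(zeros, img, subvolume_spec(c(15, 0, 0), 4), cfg)
  expect_equal(r0$enlargements, 0L)
  expect_true(r0$gamma_ok)
  # a tight cube on a tube (L = 2R) must enlarge at least once:
  # the cylinder fills pi/4 > gamma* of the cube
  seg <- oracle_segmenter(threshold = 0.5, smooth_sigma = 0)
  rt <- enlarge_until_ok(seg, img, subvolume_spec(c(15, 0, 0), 6), cfg)
  expect_gte(rt$enlargements, 1L)
})

test_that("step points land at the configured arclength fraction", {
  cfg <- tracer_config() # step_fraction 0.8
  straight <- centerline_tree(list(list(
    points = cbind(seq(0, 10, by = 0.5), 0, 0), radius = rep(1.5, 21))))
  cands <- choose_step_points(straight, cfg)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$point, c(8, 0, 0), tolerance = 1e-9)
  expect_equal(cands[[1]]$tangent, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(cands[[1]]$radius, 1.5)
  # two branches give two candidates; zero-length branches are dropped
  two <- centerline_tree(list(
    list(points = cbind(seq(0, 10, by = 0.5), 0, 0), radius = rep(1.5, 21)),
    list(points = cbind(0, seq(0, 5, by = 0.5), 0), radius = rep(1, 11)),
    list(points = matrix(c(1, 1, 1), 1), radius = 1)))
  expect_length(choose_step_points(two, cfg), 2L)
})

test_that("the bifurcation queue prioritizes large radii with stable ties", {
  cand <- function(p, r, tg = c(1, 0, 0)) list(point = p, tangent = tg, radius = r)
  u1 <- update_queue(list(), list(cand(c(0, 0, 0), 3), cand(c(10, 0, 0), 1)))
  expect_equal(u1$continue$radius, 3)
  expect_length(u1$queue, 1L)
  expect_equal(u1$queue[[1]]$radius, 1)
  # pushing reorders the queue by radius; the largest candidate continues
  u2 <- update_queue(u1$queue,
                     list(cand(c(5, 5, 5), 2.0), cand(c(20, 0, 0), 5),
                          cand(c(0, 20, 0), 2)),
                     next_id = u1$next_id)
  expect_equal(vapply(u2$queue, function(q) q$radius, numeric(1)), c(2, 2, 1))
  expect_equal(u2$continue$radius, 5)
  # radius tie: earlier-discovered entry first (stable sort)
  u3 <- update_queue(list(),
                     list(cand(c(0, 0, 0), 2), cand(c(9, 0, 0), 1),
                          cand(c(0, 9, 0), 1)))
  expect_equal(vapply(u3$queue, function(q) q$id, integer(1)), c(1L, 2L))
  # duplicate detection: a candidate within 2 radii of a queued entry is dropped
  u4 <- update_queue(u3$queue, list(cand(c(30, 0, 0), 3), cand(c(9.5, 0, 0), 1)),
                     next_id = u3$next_id)
  expect_equal(u4$deduped, 1L)
  # near-equal radii: alignment with the travel direction breaks the tie
  u5 <- update_queue(list(),
                     list(cand(c(0, 1, 0), 1.55, tg = c(0, 1, 0)),
                          cand(c(0, -1, 0), 1.6, tg = c(0, -1, 0))),
                     current_tangent = c(0, 1, 0))
  expect_equal(u5$continue$tangent, c(0, 1, 0))
})

test_that("already_traced triggers only on well-covered regions", {
  grid <- seg_map(array(0, c(20, 20, 20)), spacing = c(1, 1, 1))
  expect_false(already_traced(grid, c(10, 10, 10), 3))
  full <- seg_map(array(1, c(20, 20, 20)), spacing = c(1, 1, 1))
  expect_true(already_traced(full, c(10, 10, 10), 3))
  # partial coverage below the trigger fraction stays false
  half <- array(0, c(20, 20, 20)); half[1:10, , ] <- 1
  expect_false(already_traced(seg_map(half), c(10, 10, 10), 3, overlap = 0.9))
})

test_that("tracing is deterministic and honours the radius carry-over rule", {
  ph <- std_suite$straight
  seed <- trace_seed(c(3, 0, 0), c(1, 0, 0), 2)
  seg <- oracle_segmenter()
  r1 <- run_trace(ph$image, seed, seg, tracer_config(), finalize = FALSE)
  r2 <- run_trace(ph$image, seed, seg, tracer_config(), finalize = FALSE)
  expect_identical(r1$step_log, r2$step_log)
  # each step's cube side is 5 * mean(current, previous radius) (verified
  # from the step log: side_k = 5 * (r_k-1 + r_k-2) / 2 up to enlargement)
  ok <- r1$step_log[r1$step_log$event == "step_ok", ]
  radii <- c(2, ok$radius) # seed radius first
  for (k in seq_len(nrow(ok))) {
    r_prev2 <- if (k == 1) 2 else radii[k - 1]
    expected <- 5 * (radii[k] + r_prev2) / 2
    expect_equal(ok$side[k], expected, tolerance = 0.3) # enlargement slack
  }
  # seed outside the image errors
  expect_error(run_trace(ph$image, trace_seed(c(500, 0, 0), c(1, 0, 0), 2), seg),
               class = "vt_validation_error")
})
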