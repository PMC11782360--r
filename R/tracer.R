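#' Seed for tracing
#'
#' A starting location inside a vessel, a unit direction pointing along the
#' vessel, and a rough radius estimate — the only user input the tracer
#' needs.
#'
#' @param point length-3 mm point inside the vessel.
#' @param direction length-3 vector along the vessel (normalized internally).
#' @param radius radius estimate in mm, positive.
#' @return a `trace_seed`.
#' @export
trace_seed <- function(point, direction, radius) {
  direction <- as.numeric(direction)
  nd <- sqrt(sum(direction^2))
  vt_validate(nd > 0, "`direction` must be nonzero")
  vt_validate(is.numeric(radius) && length(radius) == 1L && radius > 0,
              "`radius` must be a single positive number")
  structure(list(point = as.numeric(point), direction = direction / nd,
                 radius = as.numeric(radius)),
            class = "trace_seed")
}

#' Tracer configuration
#'
#' All knobs of the stepping engine. Defaults follow the published
#' procedure where one is stated: subvolumes are five radii wide
#' (`size_multiplier`), steps land at 80% along each local centerline branch
#' (`step_fraction`), up to three consecutive "chances" are taken after a
#' local failure (`max_chances`), and tracing stops at 500 total steps
#' (`n_max`), below a 0.5 mm radius (`r_min`), or after `nb_max` branches.
#' The subvolume is enlarged (by `enlarge_factor`, at most
#' `max_enlargements` times) while more than `gamma_star` of its voxels are
#' predicted vessel. Retracing of already-segmented regions is checked every
#' `retrace_check_period` steps against past branches only, ignoring the
#' current branch's last `retrace_buffer_steps` contributions.
#'
#' @param size_multiplier cube side per unit mean radius.
#' @param gamma_star vessel-fraction cutoff that triggers enlargement.
#' @param max_chances consecutive chances before a branch dies.
#' @param step_fraction arclength fraction of each branch to step to.
#' @param n_max total step budget.
#' @param r_min minimum radius (mm) to keep tracing a branch.
#' @param nb_max maximum number of branches (`Inf` to disable).
#' @param enlarge_factor,max_enlargements subvolume enlargement schedule.
#' @param retrace_check_period,retrace_overlap,retrace_buffer_steps
#'   retracing-prevention schedule, trigger fraction, and current-branch
#'   buffer.
#' @param max_outside_fraction passed to [extract_subvolume()].
#' @param queue_dedupe_radii skip queueing a bifurcation within this many
#'   radii of an already-queued one.
#' @return a `tracer_config`.
#' @export
tracer_config <- function(size_multiplier = 5, gamma_star = 0.5,
                          max_chances = 3L, step_fraction = 0.8,
                          n_max = 500L, r_min = 0.5, nb_max = 15L,
                          enlarge_factor = 1.25, max_enlargements = 4L,
                          retrace_check_period = 5L, retrace_overlap = 0.9,
                          retrace_buffer_steps = 3L,
                          max_outside_fraction = 0,
                          queue_dedupe_radii = 2) {
  vt_validate(size_multiplier > 0 && gamma_star > 0 && gamma_star <= 1,
              "`size_multiplier` must be positive and `gamma_star` in (0, 1]")
  vt_validate(step_fraction > 0 && step_fraction <= 1,
              "`step_fraction` must be in (0, 1]")
  vt_validate(max_chances >= 1L && n_max >= 1L && r_min > 0,
              "`max_chances`, `n_max`, `r_min` must be positive")
  structure(list(size_multiplier = size_multiplier, gamma_star = gamma_star,
                 max_chances = as.integer(max_chances),
                 step_fraction = step_fraction,
                 n_max = as.integer(n_max), r_min = r_min, nb_max = nb_max,
                 enlarge_factor = enlarge_factor,
                 max_enlargements = as.integer(max_enlargements),
                 retrace_check_period = as.integer(retrace_check_period),
                 retrace_overlap = retrace_overlap,
                 retrace_buffer_steps = as.integer(retrace_buffer_steps),
                 max_outside_fraction = max_outside_fraction,
                 queue_dedupe_radii = queue_dedupe_radii),
            class = "tracer_config")
}

#' Side length of the next subvolume
#'
#' `L = m * (r_i + r_{i-1}) / 2`: five (by default) times the mean of the
#' current and previous radius estimates, so a single underestimated radius
#' cannot collapse the subvolume.
#'
#' @param r_i current radius estimate (mm).
#' @param r_prev previous step's radius estimate (mm; the seed radius on the
#'   first step).
#' @param multiplier cube side per unit mean radius.
#' @return side length in mm.
#' @export
next_side_length <- function(r_i, r_prev, multiplier = 5) {
  vt_validate(is.numeric(r_i) && is.numeric(r_prev) && r_i > 0 && r_prev > 0,
              "radii must be positive")
  multiplier * (r_i + r_prev) / 2
}

#' Advance one radius along the tangent (a "chance")
#'
#' After a local failure (empty segmentation, missing outlet, unreachable
#' target or stalled centerline) the tracer moves one radius further along
#' the current tangent and retries. At most `max_chances` consecutive
#' chances are allowed; the counter resets on any successful step.
#'
#' @param p current point (mm).
#' @param tangent unit direction of travel.
#' @param radius current radius estimate (mm).
#' @param chances consecutive chances already taken.
#' @param max_chances the allowance.
#' @return list with the advanced `point` and the incremented `chances`;
#'   signals a `vt_branch_dead` condition when the allowance is exhausted.
#' @export
take_chance <- function(p, tangent, radius, chances = 0L, max_chances = 3L) {
  if (chances >= max_chances)
    vt_stop(sprintf("branch terminated after %d consecutive chances", chances),
            "vt_branch_dead")
  list(point = as.numeric(p) + radius * as.numeric(tangent),
       chances = chances + 1L)
}

#' Enlarge a subvolume until the predicted vessel fraction is acceptable
#'
#' Segments the subvolume and, while the fraction `gamma` of voxels
#' predicted vessel (probability >= 0.5) exceeds `gamma_star` — indicating
#' the vessel dominates the cube, i.e. the cube is too small — multiplies
#' the side by `enlarge_factor` and re-segments, up to `max_enlargements`
#' times. If an enlargement pushes the cube out of the image, the last
#' in-bounds result is returned; an initial out-of-bounds cube propagates.
#'
#' @param segmenter a [as_segmenter()] function.
#' @param image the global [image_volume()].
#' @param spec initial [subvolume_spec()].
#' @param cfg a [tracer_config()].
#' @return list with `spec`, `prob` ([seg_map()]), `gamma`, `enlargements`,
#'   and `gamma_ok` (`FALSE` when the budget ran out with `gamma` still
#'   above the cutoff).
#' @export
enlarge_until_ok <- function(segmenter, image, spec, cfg = tracer_config()) {
  segment_at <- function(sp) {
    sub <- extract_subvolume(image, sp, cfg$max_outside_fraction)
    prob <- segmenter(sub)
    vt_validate(inherits(prob, "image_volume") && same_grid(prob, sub),
                "segmenter violated its contract: output grid differs from input")
    list(spec = sp, prob = prob, gamma = mean(prob$data >= 0.5))
  }
  cur <- segment_at(spec) # initial out-of-bounds propagates
  n <- 0L
  while (cur$gamma > cfg$gamma_star && n < cfg$max_enlargements) {
    n <- n + 1L
    bigger <- subvolume_spec(spec$center, cur$spec$side * cfg$enlarge_factor)
    nxt <- tryCatch(segment_at(bigger), vt_out_of_bounds = function(e) NULL)
    if (is.null(nxt)) break
    cur <- nxt
  }
  list(spec = cur$spec, prob = cur$prob, gamma = cur$gamma,
       enlargements = n, gamma_ok = cur$gamma <= cfg$gamma_star)
}

#' Choose stepping points along local centerline branches
#'
#' For each branch of a local centerline tree (ordered source to target),
#' picks the point at arclength fraction `step_fraction` (80% by default)
#' from the source, together with the local tangent (central differences)
#' and the interpolated radius there. Branches shorter than two voxels are
#' dropped.
#'
#' @param tree a [centerline_tree()].
#' @param cfg a [tracer_config()].
#' @param min_length branches shorter than this (mm) are dropped; defaults
#'   to twice the minimum grid spacing stored with the tree points' frame —
#'   pass explicitly when known.
#' @return list of candidates, each `list(point, tangent, radius)`, in
#'   branch order.
#' @export
choose_step_points <- function(tree, cfg = tracer_config(), min_length = 0) {
  out <- list()
  for (b in tree$branches) {
    if (nrow(b$points) < 2L) next
    seg <- sqrt(rowSums(diff(b$points)^2))
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    if (total <= min_length) next
    si <- cfg$step_fraction * total
    pt <- vapply(1:3, function(a) stats::approx(s, b$points[, a], xout = si)$y,
                 numeric(1))
    rad <- stats::approx(s, b$radius, xout = si)$y
    tg <- polyline_tangents(b$points)
    j <- findInterval(si, s)
    j <- min(max(j, 1L), nrow(b$points))
    out[[length(out) + 1L]] <- list(point = pt, tangent = tg[j, ], radius = rad)
  }
  out
}

#' Queue update after a successful step
#'
#' The largest-radius candidate is chosen for continued tracing; the rest
#' are pushed onto the bifurcation queue, which is kept sorted by radius
#' (descending, stable in discovery order) so the largest vessels are traced
#' first. Radius estimates carry measurement noise, so candidates whose
#' radii lie within `tie_tolerance` (relative) of the largest are treated as
#' a tie and the one best aligned with the current direction of travel
#' continues — without this, a symmetric bifurcation seen in two consecutive
#' subvolumes would flip the tracer between daughters. Candidates within
#' `dedupe_radii` local radii of an entry already in the queue are dropped
#' as duplicate detections of the same bifurcation.
#'
#' @param queue list of queue entries (`point`, `tangent`, `radius`, `id`).
#' @param candidates candidate list from [choose_step_points()].
#' @param dedupe_radii proximity (in radii) under which a push is a
#'   duplicate.
#' @param next_id discovery counter for stable ordering.
#' @param current_tangent unit direction of travel (alignment tie-break);
#'   `NULL` keeps pure radius ordering.
#' @param tie_tolerance relative radius difference treated as a tie.
#' @return list with `continue` (the chosen candidate), the new `queue`,
#'   `pushed` (list of pushed entries), `deduped` count, and the advanced
#'   `next_id`.
#' @export
update_queue <- function(queue, candidates, dedupe_radii = 2, next_id = 1L,
                         current_tangent = NULL, tie_tolerance = 0.2) {
  vt_validate(length(candidates) >= 1L, "need at least one step candidate")
  rads <- vapply(candidates, function(cand) cand$radius, numeric(1))
  ord <- order(-rads) # stable: ties keep discovery order
  best <- ord[1]
  if (!is.null(current_tangent) && length(candidates) > 1L) {
    tied <- which(rads >= (1 - tie_tolerance) * rads[best])
    if (length(tied) > 1L) {
      align <- vapply(tied, function(k)
        sum(candidates[[k]]$tangent * current_tangent), numeric(1))
      best <- tied[which.max(align)]
      ord <- c(best, setdiff(ord, best))
    }
  }
  continue <- candidates[[best]]
  pushed <- list(); deduped <- 0L
  for (k in ord[-1]) {
    cand <- candidates[[k]]
    dup <- any(vapply(queue, function(q)
      sqrt(sum((q$point - cand$point)^2)) < dedupe_radii * cand$radius,
      logical(1)))
    if (dup) { deduped <- deduped + 1L; next }
    ent <- list(point = cand$point, tangent = cand$tangent,
                radius = cand$radius, id = next_id)
    queue[[length(queue) + 1L]] <- ent
    pushed[[length(pushed) + 1L]] <- ent
    next_id <- next_id + 1L
  }
  if (length(queue) > 1L) {
    qr <- vapply(queue, function(q) q$radius, numeric(1))
    qid <- vapply(queue, function(q) q$id, integer(1))
    queue <- queue[order(-qr, qid)]
  }
  list(continue = continue, queue = queue, pushed = pushed,
       deduped = deduped, next_id = next_id)
}

#' Has a candidate region already been traced?
#'
#' Checks the fraction of a ball (of the local vessel radius, centered on
#' the candidate point) already covered by the supplied fused vessel mask.
#' The tracer calls this with the union of *past* branches' predictions
#' only — excluding the current branch's most recent steps — so a branch
#' never trips over its own freshly fused trail.
#'
#' @param past_mask binary [seg_map()] of already-fused vessel voxels.
#' @param point candidate point (mm).
#' @param radius local radius (mm).
#' @param overlap trigger fraction.
#' @return `TRUE` if the covered fraction exceeds `overlap`.
#' @export
already_traced <- function(past_mask, point, radius, overlap = 0.9) {
  d <- dim(past_mask$data)
  ax <- axis_coords(past_mask)
  ir <- lapply(1:3, function(a)
    which(ax[[a]] >= point[a] - radius & ax[[a]] <= point[a] + radius))
  if (any(vapply(ir, length, integer(1)) == 0L)) return(FALSE)
  ball <- outer(outer((ax[[1]][ir[[1]]] - point[1])^2,
                      (ax[[2]][ir[[2]]] - point[2])^2, "+"),
                (ax[[3]][ir[[3]]] - point[3])^2, "+") <= radius^2
  nball <- sum(ball)
  if (nball == 0L) return(FALSE)
  sub <- past_mask$data[ir[[1]], ir[[2]], ir[[3]]]
  sum(sub[ball] > 0.5) / nball > overlap
}

#' Trace a vascular tree from a single seed
#'
#' The main sequential loop. Starting at the seed, each iteration sizes a
#' cubic subvolume from the running radius estimates, extracts and segments
#' it (enlarging while the vessel dominates the cube), converts the local
#' prediction to a surface, finds the truncation boundaries, classifies
#' source and targets, extracts local centerlines by fast-marching plus
#' gradient descent, fuses the prediction into the global accumulator, and
#' steps to 80% along the continuing branch; extra branches are queued by
#' radius as bifurcations. Local failures grant up to three consecutive
#' "chances" (advance one radius and retry). A branch ends at the image
#' boundary, below the minimum radius, after exhausted chances, or when a
#' region was already traced; the trace ends when the queue is empty or the
#' step/branch budget is spent.
#'
#' @param image the global [image_volume()].
#' @param seed a [trace_seed()].
#' @param segmenter a segmenter satisfying [as_segmenter()].
#' @param cfg a [tracer_config()].
#' @param fusion a [fusion_config()].
#' @param finalize if `TRUE` (default) also threshold, filter, mesh and
#'   smooth the fused map.
#' @return a `trace_result`: list with `probability` (fused [seg_map()]),
#'   `binary`, `mesh` (when finalized), `step_log` (data.frame), `paths`
#'   (list of per-branch stepping polylines with radii), `accumulator`,
#'   and counts `n_steps`, `n_branches`.
#' @export
run_trace <- function(image, seed, segmenter, cfg = tracer_config(),
                      fusion = fusion_config(), finalize = TRUE) {
  vt_validate(inherits(seed, "trace_seed"), "`seed` must come from trace_seed()")
  d <- dim(image$data)
  sv <- round(world_to_voxel(image, seed$point))
  if (any(sv < 1) || any(sv > d))
    vt_stop("seed point lies outside the image", "vt_validation_error")

  acc <- global_accumulator(image, fusion)
  past <- array(FALSE, d)       # fused binary of completed branches
  cur_contribs <- list()        # this branch's contributions (lo, hi, bin)
  logrows <- list()
  log_event <- function(branch, event, reason = NA_character_, p = c(NA, NA, NA),
                        radius = NA_real_, side = NA_real_, gamma = NA_real_,
                        n_caps = NA_integer_, chances = NA_integer_) {
    logrows[[length(logrows) + 1L]] <<- data.frame(
      step = length(logrows) + 1L, branch = branch, event = event,
      reason = reason, x = p[1], y = p[2], z = p[3], radius = radius,
      side = side, gamma = gamma, n_caps = n_caps, chances = chances,
      stringsAsFactors = FALSE)
  }

  queue <- list()
  next_id <- 1L
  branch <- 1L
  n_steps <- 0L
  n_success <- 0L
  paths <- list()
  cur_path <- list(list(point = seed$point, radius = seed$radius))

  st <- list(p = seed$point, tg = seed$direction, r = seed$radius,
             r_prev = seed$radius,
             prev_point = seed$point - seed$radius * seed$direction,
             chances = 0L, steps = 0L)
  log_event(branch, "init", p = st$p, radius = st$r)

  commit_branch <- function() {
    for (ct in cur_contribs)
      past[ct$lo[1]:ct$hi[1], ct$lo[2]:ct$hi[2], ct$lo[3]:ct$hi[3]] <<-
        past[ct$lo[1]:ct$hi[1], ct$lo[2]:ct$hi[2], ct$lo[3]:ct$hi[3]] | ct$bin
    cur_contribs <<- list()
    paths[[length(paths) + 1L]] <<- cur_path
    cur_path <<- list()
  }
  past_plus_old_current <- function() {
    m <- past
    nold <- length(cur_contribs) - cfg$retrace_buffer_steps
    if (nold > 0)
      for (ct in cur_contribs[seq_len(nold)])
        m[ct$lo[1]:ct$hi[1], ct$lo[2]:ct$hi[2], ct$lo[3]:ct$hi[3]] <-
          m[ct$lo[1]:ct$hi[1], ct$lo[2]:ct$hi[2], ct$lo[3]:ct$hi[3]] | ct$bin
    seg_map(array(as.numeric(m), d), image$spacing, image$origin, binary = TRUE)
  }

  end_branch <- function(reason) {
    log_event(branch, "branch_end", reason = reason, p = st$p, radius = st$r,
              chances = st$chances)
    commit_branch()
  }
  chance_or_die <- function(reason) {
    adv <- tryCatch(take_chance(st$p, st$tg, st$r, st$chances, cfg$max_chances),
                    vt_branch_dead = function(e) NULL)
    if (is.null(adv)) {
      end_branch(paste0("chances_exhausted:", reason))
      if (branch == 1L && n_success == 0L)
        vt_stop(sprintf("tracing failed at the first step (%s) after all chances",
                        reason), "vt_trace_failed")
      return(FALSE)
    }
    st$p <<- adv$point
    st$chances <<- adv$chances
    log_event(branch, "chance", reason = reason, p = st$p, radius = st$r,
              chances = st$chances)
    TRUE
  }

  branch_alive <- TRUE
  repeat {
    if (!branch_alive) {
      if (length(queue) == 0L || branch >= cfg$nb_max || n_steps >= cfg$n_max)
        break
      ent <- queue[[1L]]
      queue <- queue[-1L]
      log_event(branch + 1L, "queue_pop", p = ent$point, radius = ent$radius)
      branch <- branch + 1L
      st <- list(p = ent$point, tg = ent$tangent, r = ent$radius,
                 r_prev = ent$radius,
                 prev_point = ent$point - ent$radius * ent$tangent,
                 chances = 0L, steps = 0L)
      cur_path <- list(list(point = ent$point, radius = ent$radius))
      branch_alive <- TRUE
      next
    }

    if (n_steps >= cfg$n_max) { end_branch("n_max"); branch_alive <- FALSE; next }
    if (st$r < cfg$r_min) { end_branch("r_min"); branch_alive <- FALSE; next }

    n_steps <- n_steps + 1L
    st$steps <- st$steps + 1L

    # periodic retracing prevention against past branches (buffered): both
    # the current neighbourhood and a forward-projected one must already be
    # covered, so a young branch exiting passively-covered territory survives
    if (st$steps > 1L && st$steps %% cfg$retrace_check_period == 0L) {
      pastmap <- past_plus_old_current()
      if (already_traced(pastmap, st$p, st$r, cfg$retrace_overlap) &&
          already_traced(pastmap, st$p + 2 * st$r * st$tg, st$r,
                         cfg$retrace_overlap)) {
        end_branch("retraced"); branch_alive <- FALSE; next
      }
    }

    L <- next_side_length(st$r, st$r_prev, cfg$size_multiplier)
    spec <- subvolume_spec(st$p, L)

    seg <- tryCatch(enlarge_until_ok(segmenter, image, spec, cfg),
                    vt_out_of_bounds = function(e) e)
    if (inherits(seg, "vt_out_of_bounds")) {
      end_branch("out_of_bounds"); branch_alive <- FALSE; next
    }
    prob <- seg$prob
    binarr <- prob$data >= 0.5
    if (!any(binarr)) {
      if (!chance_or_die("empty_segmentation")) branch_alive <- FALSE
      next
    }

    # fuse every nonempty prediction, even if centerline extraction fails:
    # the assembly keeps all local evidence
    acc <- accumulate(acc, prob, seg$spec)
    ir <- attr(extract_subvolume(image, seg$spec, cfg$max_outside_fraction),
               "index_range")
    cur_contribs[[length(cur_contribs) + 1L]] <-
      list(lo = ir[1, ], hi = ir[2, ], bin = binarr)

    geom <- tryCatch({
      mesh <- extract_surface(prob, iso = 0.5)
      caps <- find_caps(mesh)
      if (length(caps) < 2L)
        vt_stop("fewer than two truncation boundaries", "vt_no_outlet")
      caps <- assign_source_target(caps, st$prev_point)
      binmap <- seg_map(array(as.numeric(binarr), dim(prob$data)),
                        prob$spacing, prob$origin, binary = TRUE)
      speed <- build_speed(binmap)
      field <- solve_eikonal(speed, caps[[1L]]$center)
      targets <- do.call(rbind, lapply(caps[-1L], function(cp) cp$center))
      tree <- trace_centerline(field, targets)
      cands <- choose_step_points(tree, cfg,
                                  min_length = 2 * min(image$spacing))
      list(tree = tree, cands = cands, n_caps = length(caps))
    }, vt_error = function(e) e)

    if (inherits(geom, "vt_error")) {
      reason <- intersect(class(geom), c("vt_empty_segmentation", "vt_no_outlet",
                                         "vt_unreachable_target", "vt_stall_error"))
      reason <- if (length(reason)) sub("^vt_", "", reason[1]) else "local_failure"
      if (!chance_or_die(reason)) branch_alive <- FALSE
      next
    }
    if (length(geom$cands) == 0L) {
      if (!chance_or_die("no_step_candidates")) branch_alive <- FALSE
      next
    }

    upd <- update_queue(queue, geom$cands, cfg$queue_dedupe_radii, next_id,
                        current_tangent = st$tg)
    queue <- upd$queue
    next_id <- upd$next_id
    for (ent in upd$pushed)
      log_event(branch, "queue_push", p = ent$point, radius = ent$radius,
                n_caps = geom$n_caps)

    n_success <- n_success + 1L
    st$chances <- 0L
    st$prev_point <- st$p
    st$r_prev <- st$r
    st$p <- upd$continue$point
    st$r <- upd$continue$radius
    st$tg <- upd$continue$tangent
    cur_path[[length(cur_path) + 1L]] <- list(point = st$p, radius = st$r)
    log_event(branch, "step_ok", p = st$p, radius = st$r, side = seg$spec$side,
              gamma = seg$gamma, n_caps = geom$n_caps, chances = 0L)
  }

  step_log <- do.call(rbind, logrows)
  out <- list(probability = fused_map(acc), accumulator = acc,
              step_log = step_log, paths = paths,
              n_steps = n_steps, n_branches = branch)
  if (finalize && any(out$probability$data >= fusion$threshold)) {
    fin <- finalize_assembly(acc)
    out$binary <- fin$binary
    out$mesh <- fin$mesh
  }
  class(out) <- "trace_result"
  out
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("<trace_result> %d step(s), %d branch(es)\n", x$n_steps, x$n_branches))
  ends <- x$step_log[x$step_log$event == "branch_end", , drop = FALSE]
  if (nrow(ends))
    cat("  branch ends:", paste(ends$reason, collapse = ", "), "\n")
  if (!is.null(x$binary))
    cat(sprintf("  fused vessel voxels: %d\n", sum(x$binary$data)))
  invisible(x)
}
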