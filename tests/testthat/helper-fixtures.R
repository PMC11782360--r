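# Shared fixtures, built once per test run.

# The five-case phantom suite under the default imaging conditions.
std_suite <- make_standard_suite()

# A clean (no blur, no noise) straight tube for geometric oracles.
clean_tube_spec <- tree_spec(
  list(list(start = c(0, 0, 0), end = c(30, 0, 0), radius = 3, parent = NA)),
  blur_sigma = 0, noise_sigma = 0, spacing = 0.5, margin_mm = c(2, 4, 4),
  seed = 7L)
clean_tube <- make_phantom(clean_tube_spec)

# Binary ball mask of a given voxel radius in a cubic grid.
make_ball <- function(r = 5, n = 2 * r + 11, center = rep((n + 1) / 2, 3),
                      spacing = c(1, 1, 1)) {
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  arr <- array(as.numeric(rowSums(sweep(g, 2, center)^2) <= r^2), c(n, n, n))
  seg_map(arr, spacing = spacing)
}

# Random blob mask (union of balls, largest 6-connected component), used by
# the eikonal/Dijkstra and Hausdorff oracle tests.
random_blob <- function(n = 20, balls = 4) {
  d <- rep(n, 3)
  m <- array(FALSE, d)
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  ctr <- matrix(stats::runif(3 * balls, n * 0.25, n * 0.8), balls, 3)
  rad <- stats::runif(balls, n * 0.15, n * 0.3)
  for (b in seq_len(balls))
    m[g[rowSums(sweep(g, 2, ctr[b, ])^2) <= rad[b]^2, ]] <- TRUE
  largest_component(seg_map(array(as.numeric(m), d)), connectivity = 6L)
}

# Independent 26-neighbour Dijkstra arrival times on a speed field, used as
# the brute-force oracle for the fast-marching solver. Edge weights integrate
# the slowness 1/F along each edge with the log-mean (exact for a linearly
# varying speed).
dijkstra_times <- function(F, src_lin) {
  d <- dim(F$data)
  w <- which(F$data > 0)
  id <- seq_along(w)
  names(id) <- w
  ai <- arrayInd(w, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  edges <- NULL; wts <- NULL
  for (k in seq_len(nrow(nb))) {
    to <- sweep(ai, 2, nb[k, ], "+")
    ok <- to[, 1] >= 1 & to[, 1] <= d[1] & to[, 2] >= 1 & to[, 2] <= d[2] &
      to[, 3] >= 1 & to[, 3] <= d[3]
    tolin <- to[ok, 1] + d[1] * ((to[ok, 2] - 1) + d[2] * (to[ok, 3] - 1))
    inmask <- tolin %in% w
    from <- w[ok][inmask]; tl <- tolin[inmask]
    len <- sqrt(sum((nb[k, ] * F$spacing)^2))
    fa <- F$data[from]; fb <- F$data[tl]
    s <- ifelse(abs(fa - fb) < 1e-9, 1 / fa, log(fb / fa) / (fb - fa))
    edges <- rbind(edges, cbind(id[as.character(from)], id[as.character(tl)]))
    wts <- c(wts, len * s)
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(gr)$weight <- wts
  dd <- igraph::distances(gr, v = id[as.character(src_lin)])[1, seq_along(w)]
  list(lin = w, t = as.numeric(dd))
}

# Brute-force boundary-set Hausdorff distance (O(n*m) all-pairs), the
# independent oracle for hausdorff_metric(). Boundary voxels are foreground
# voxels with a 6-neighbour outside the foreground (array edges count).
brute_hausdorff <- function(X, Y) {
  boundary <- function(m) {
    pts <- which(m == 1, arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(pts)), function(i) {
      p <- pts[i, ]
      for (ax in 1:3) for (dd in c(-1, 1)) {
        q <- p; q[ax] <- q[ax] + dd
        if (any(q < 1) || any(q > dim(m))) return(TRUE)
        if (m[q[1], q[2], q[3]] == 0) return(TRUE)
      }
      FALSE
    }, logical(1))
    pts[keep, , drop = FALSE]
  }
  bx <- boundary(X); by <- boundary(Y)
  dmat <- sqrt(pmax(outer(rowSums(bx^2), rowSums(by^2), "+") - 2 * bx %*% t(by), 0))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}
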