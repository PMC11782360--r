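#' The local segmenter contract
#'
#' A segmenter is any function that maps an [image_volume()] subvolume to a
#' [seg_map()] on the *same* grid with values in `[0, 1]`, deterministically
#' (any internal randomness must be seeded). Trained models plug in behind
#' this contract; the package ships an intensity-threshold oracle segmenter
#' that fulfils it exactly on two-level phantom images.
#'
#' `as_segmenter()` wraps a plain function and `get_segmenter()` resolves a
#' segmenter by name: `"oracle"` (optionally `oracle:<threshold>`), or
#' `"module:pkg::fun"` for an external plug-in.
#'
#' @param f a function `(image_volume) -> seg_map`.
#' @param name a segmenter name string.
#' @param ... passed to the segmenter factory.
#' @return a `vt_segmenter` function.
#' @export
as_segmenter <- function(f) {
  vt_validate(is.function(f), "a segmenter must be a function")
  structure(f, class = c("vt_segmenter", "function"))
}

#' @rdname as_segmenter
#' @export
get_segmenter <- function(name, ...) {
  if (grepl("^oracle", name)) {
    thr <- sub("^oracle:?", "", name)
    if (nzchar(thr)) oracle_segmenter(threshold = as.numeric(thr), ...)
    else oracle_segmenter(...)
  } else if (grepl("^module:", name)) {
    ref <- sub("^module:", "", name)
    parts <- strsplit(ref, "::", fixed = TRUE)[[1]]
    f <- if (length(parts) == 2L) getExportedValue(parts[1], parts[2]) else get(ref)
    as_segmenter(f)
  } else {
    vt_stop(sprintf("unknown segmenter: %s", name), "vt_validation_error")
  }
}

#' Intensity-threshold oracle segmenter
#'
#' A reference [as_segmenter()] implementation for synthetic and
#' high-contrast data: optional Gaussian denoising followed by a logistic
#' squashing of `(intensity - threshold) / scale`, so the output probability
#' is monotone in intensity and crosses 0.5 exactly at the threshold. On a
#' two-level phantom with the threshold midway between the levels, voxels
#' inside the vessel get probability > 0.5 and background voxels < 0.5.
#'
#' @param threshold intensity at which the probability is 0.5.
#' @param smooth_sigma Gaussian denoising sigma in mm (0 = none).
#' @param scale logistic softness in intensity units.
#' @return a `vt_segmenter` function.
#' @export
oracle_segmenter <- function(threshold = 0.5, smooth_sigma = 0.5, scale = 0.05) {
  force(threshold); force(smooth_sigma); force(scale)
  as_segmenter(function(subvolume) {
    vol <- if (smooth_sigma > 0) gaussian_smooth(subvolume, smooth_sigma) else subvolume
    p <- stats::plogis((vol$data - threshold) / scale)
    seg_map(p, spacing = vol$spacing, origin = vol$origin)
  })
}

#' Soft Dice score
#'
#' `D = 2 |Yp . Yt| / (|Yp| + |Yt|)`, with the intersection taken as the
#' elementwise product so soft probability maps are allowed; on binary maps
#' this reduces to the usual Dice overlap. Two empty maps score 1 (a
#' degenerate all-background patch is a perfect match, not a failure).
#'
#' @param Yp,Yt [seg_map()]s (or plain arrays) on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice_score <- function(Yp, Yt) {
  a <- as_seg_data(Yp, Yt)
  num <- 2 * sum(a$p * a$t)
  den <- sum(a$p) + sum(a$t)
  if (den == 0) return(1)
  num / den
}

#' Mean Bernoulli log-likelihood of a segmentation
#'
#' `CE = (1/n) sum( yt log yp + (1 - yt) log(1 - yp) )` — note this is the
#' mean log-likelihood, a non-positive number (the training loss *subtracts*
#' it, so worse predictions increase the loss). Probabilities are clamped to
#' `[eps, 1 - eps]` before the logs.
#'
#' @param Yp predicted probabilities; `Yt` binary truth, same grid.
#' @param Yt binary truth map.
#' @param eps clamp applied to `Yp` before taking logs.
#' @return scalar `<= 0`.
#' @export
cross_entropy <- function(Yp, Yt, eps = 1e-7) {
  a <- as_seg_data(Yp, Yt)
  p <- pmin(pmax(a$p, eps), 1 - eps)
  mean(a$t * log(p) + (1 - a$t) * log(1 - p))
}

as_seg_data <- function(Yp, Yt) {
  p <- if (inherits(Yp, "image_volume")) Yp$data else Yp
  t <- if (inherits(Yt, "image_volume")) Yt$data else Yt
  if (inherits(Yp, "image_volume") && inherits(Yt, "image_volume"))
    vt_validate(same_grid(Yp, Yt), "prediction and truth grids differ")
  else
    vt_validate(identical(dim(p), dim(t)), "prediction and truth grids differ")
  list(p = as.numeric(p), t = as.numeric(t))
}

#' Batch training loss
#'
#' `L = sum_i (1 - D(Yp_i, Yt_i) - CE(Yp_i, Yt_i))` over a batch: each
#' item contributes one-minus-Dice plus the negated mean log-likelihood, so
#' perfect predictions give a total of approximately zero.
#'
#' @param truths list of binary [seg_map()]s.
#' @param predictions list of predicted [seg_map()]s, same length and grids.
#' @return a `batch_loss_report`: list with per-item `dice_terms`,
#'   `ce_terms`, and the summed `total`.
#' @export
batch_loss <- function(truths, predictions) {
  vt_validate(length(truths) == length(predictions),
              "`truths` and `predictions` must have the same length")
  dice_terms <- mapply(dice_score, predictions, truths)
  ce_terms <- mapply(cross_entropy, predictions, truths)
  structure(list(dice_terms = as.numeric(dice_terms),
                 ce_terms = as.numeric(ce_terms),
                 total = sum(1 - dice_terms - ce_terms)),
            class = "batch_loss_report")
}

#' @export
print.batch_loss_report <- function(x, ...) {
  cat(sprintf("<batch_loss_report> %d item(s): mean Dice %.4f, mean CE %.4f, total loss %.4f\n",
              length(x$dice_terms), mean(x$dice_terms), mean(x$ce_terms), x$total))
  invisible(x)
}
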