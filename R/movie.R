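## Synthetic two-photon movies: each soma rendered as a Gaussian blob
## whose brightness follows its fluorescence trace, over a constant
## background with pixel noise. Used to exercise ROI extraction.

#' Field-of-view layout for a synthetic movie
#'
#' @param width,height frame size in pixels.
#' @param centers n x 2 matrix of soma centers (x, y) in pixel units.
#' @param radii soma radii in pixels (recycled to n).
#' @param background_offset constant background intensity.
#' @param noise_sd pixel noise SD.
#' @return object of class `movie_layout`.
#' @export
movie_layout <- function(width = 64L, height = 64L, centers, radii = 5,
                         background_offset = 100, noise_sd = 0) {
  centers <- matrix(as.numeric(centers), ncol = 2L)
  radii <- rep_len(as.numeric(radii), nrow(centers))
  fits <- centers[, 1] - radii >= 1 & centers[, 1] + radii <= width &
    centers[, 2] - radii >= 1 & centers[, 2] + radii <= height
  assert_that(all(fits), "somata must fit inside the frame")
  if (nrow(centers) > 1L) {
    d <- as.matrix(stats::dist(centers))
    lim <- outer(radii, radii, "+")
    diag(d) <- Inf
    assert_that(all(d > lim), "somata must not overlap")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 centers = centers, radii = radii,
                 background_offset = background_offset, noise_sd = noise_sd),
            class = "movie_layout")
}

#' Render a synthetic movie and its ROI masks
#'
#' Each frame is `background_offset` plus, per soma, a Gaussian blob
#' (sigma = radius / 2) scaled by that frame's trace value, plus white
#' pixel noise. Masks are binary disks at the soma positions.
#'
#' @param traces list of [fluor_trace()] objects, one per soma, equal
#'   lengths; trace `raw_f` values scale blob brightness linearly.
#' @param layout a [movie_layout()] with one center per trace.
#' @param seed optional RNG seed for pixel noise.
#' @return list with `stack` (height x width x frames array), `masks`
#'   (list of logical matrices), and `frame_times`.
#' @export
simulate_movie <- function(traces, layout, seed = NULL) {
  stopifnot(inherits(layout, "movie_layout"))
  assert_that(length(traces) == nrow(layout$centers),
              "one layout center per trace required")
  nframes <- length(traces[[1]]$frame_times)
  assert_that(all(vapply(traces, function(tr) length(tr$frame_times), 1L) == nframes),
              "all traces must have the same number of frames", kind = "data")
  if (!is.null(seed)) set.seed(as.integer(seed))

  xs <- matrix(rep(seq_len(layout$width), each = layout$height),
               nrow = layout$height)
  ys <- matrix(rep(seq_len(layout$height), layout$width), nrow = layout$height)
  blobs <- masks <- vector("list", length(traces))
  for (k in seq_along(traces)) {
    cx <- layout$centers[k, 1]; cy <- layout$centers[k, 2]
    r <- layout$radii[k]
    d2 <- (xs - cx)^2 + (ys - cy)^2
    blobs[[k]] <- exp(-d2 / (2 * (r / 2)^2))
    masks[[k]] <- d2 <= r^2
  }

  stack <- array(layout$background_offset,
                 dim = c(layout$height, layout$width, nframes))
  for (f in seq_len(nframes)) {
    frame <- stack[, , f]
    for (k in seq_along(traces))
      frame <- frame + traces[[k]]$raw_f[f] * blobs[[k]]
    if (layout$noise_sd > 0)
      frame <- frame + stats::rnorm(length(frame), 0, layout$noise_sd)
    stack[, , f] <- frame
  }
  list(stack = stack, masks = masks, frame_times = traces[[1]]$frame_times)
}

#' Write a movie stack and masks as TIFF files
#'
#' The stack is written as a 16-bit multi-page TIFF (one page per frame,
#' intensities scaled by `scale_max`), masks as single-page 8-bit TIFFs.
#'
#' @param movie result of [simulate_movie()].
#' @param stack_path output path for the multi-page stack.
#' @param mask_paths character vector of mask output paths (one per ROI),
#'   or `NULL` to skip masks.
#' @param scale_max intensity mapped to the 16-bit maximum.
#' @return `stack_path`, invisibly.
#' @export
write_movie_tiff <- function(movie, stack_path, mask_paths = NULL,
                             scale_max = NULL) {
  scale_max <- scale_max %||% max(movie$stack)
  nframes <- dim(movie$stack)[3]
  pages <- lapply(seq_len(nframes), function(f)
    pmin(pmax(movie$stack[, , f] / scale_max, 0), 1))
  tiff::writeTIFF(pages, stack_path, bits.per.sample = 16L)
  if (!is.null(mask_paths)) {
    assert_that(length(mask_paths) == length(movie$masks),
                "one mask path per ROI required")
    for (k in seq_along(movie$masks))
      tiff::writeTIFF(movie$masks[[k]] * 1.0, mask_paths[k],
                      bits.per.sample = 8L)
  }
  invisible(stack_path)
}

#' Read a multi-page TIFF stack into an array
#'
#' @param path TIFF file path.
#' @return height x width x frames numeric array (values in \[0, 1\] as
#'   stored by [write_movie_tiff()]).
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' Read a binary ROI mask from a single-page TIFF
#'
#' @param path TIFF file path.
#' @return logical matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
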