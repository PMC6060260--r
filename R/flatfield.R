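# Flat-field (illumination) correction, known-layout grid stitching, and
# ratiometric green/red quantification.

#' Mosaic tile layout
#'
#' A regular grid of tiles with a stated overlap fraction between
#' neighbors. `origins` holds the 0-based (row, col) of each tile's
#' top-left pixel in the mosaic, in row-major tile order.
#'
#' @param rows,cols Grid counts (>= 1).
#' @param tile_shape `c(H, W)` of every tile.
#' @param overlap_frac Fraction of tile shared with each neighbor, in
#'   `[0, 1)`.
#' @param origins Optional n x 2 matrix of tile origins; computed from the
#'   nominal stride `tile * (1 - overlap_frac)` (rounded) when absent.
#' @return An object of class `mosaic_layout` with `mosaic_shape` filled
#'   in.
#' @export
mosaic_layout <- function(rows, cols, tile_shape, overlap_frac = 0,
                          origins = NULL) {
  stopifnot(rows >= 1, cols >= 1, overlap_frac >= 0, overlap_frac < 1)
  th <- tile_shape[1]; tw <- tile_shape[2]
  if (is.null(origins)) {
    sr <- th * (1 - overlap_frac); sc <- tw * (1 - overlap_frac)
    grid <- expand.grid(r = seq_len(rows) - 1, c = seq_len(cols) - 1)
    grid <- grid[order(grid$r, grid$c), ]
    origins <- cbind(round(grid$r * sr), round(grid$c * sc))
  }
  origins <- matrix(as.integer(origins), ncol = 2)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 tile_shape = c(as.integer(th), as.integer(tw)),
                 overlap_frac = overlap_frac, origins = origins,
                 mosaic_shape = c(max(origins[, 1]) + th,
                                  max(origins[, 2]) + tw)),
            class = "mosaic_layout")
}

#' Plan a tile grid that exactly covers a truth image
#'
#' Tile size solves `tile * (n - (n - 1) * overlap) = extent` per axis
#' (rounded up); origins are spread evenly with the last tile flush with
#' the far edge, so the tiles cover the image exactly.
#'
#' @param truth_shape `c(H, W)` of the image to cover.
#' @param rows,cols Grid counts.
#' @param overlap_frac Overlap fraction in `(0, 1)` (0 allowed for abutting
#'   tiles).
#' @return A [mosaic_layout()].
#' @export
plan_mosaic_layout <- function(truth_shape, rows, cols, overlap_frac = 0.1) {
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("parameter error: overlap_frac must be in [0, 1)")
  }
  size1 <- function(extent, n) {
    tile <- ceiling(extent / (n - (n - 1) * overlap_frac))
    org <- if (n == 1) 0 else round(seq(0, extent - tile, length.out = n))
    list(tile = tile, org = org)
  }
  rr <- size1(truth_shape[1], rows)
  cc <- size1(truth_shape[2], cols)
  grid <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  grid <- grid[order(grid$r, grid$c), ]
  origins <- cbind(rr$org[grid$r], cc$org[grid$c])
  mosaic_layout(rows, cols, c(rr$tile, cc$tile), overlap_frac,
                origins = origins)
}

# Separable Gaussian blur with replicate (edge-extend) padding.
# `support` is the full kernel width in pixels (odd); defaults to the
# conventional 6-sigma support.
.gaussian_blur <- function(img, sigma, support = NULL) {
  if (is.null(support)) support <- 2 * ceiling(3 * sigma) + 1
  half <- (support - 1) %/% 2
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(rep(1, half), 1:h, rep(h, half)),
             c(rep(1, half), 1:w, rep(w, half)), drop = FALSE]
  tmp <- matrix(0, h, w + 2 * half)       # vertical pass
  for (i in seq_len(support)) {
    tmp <- tmp + k[i] * pad[(i):(i + h - 1), , drop = FALSE]
  }
  out <- matrix(0, h, w)                  # horizontal pass
  for (i in seq_len(support)) {
    out <- out + k[i] * tmp[, (i):(i + w - 1), drop = FALSE]
  }
  out
}

#' Build a flat-field reference from a set of tiles
#'
#' The tiles (edge tiles excluded by the caller) are averaged pixelwise,
#' the average is smoothed with a Gaussian filter of the stated kernel
#' width to remove all high-frequency structure, and the result is divided
#' by its own mean so the reference averages 1. The outcome approximates
#' the illumination pattern of the excitation source.
#'
#' @param tiles List of equally shaped tile matrices (>= 2; one tile is
#'   accepted with a warning).
#' @param kernel_px Full Gaussian kernel width in pixels (default 121);
#'   the Gaussian sigma is `kernel_px / 6`.
#' @return `list(image =, kernel_px =)` of class `flatfield_reference`;
#'   `image` is strictly positive with mean 1.
#' @export
build_flatfield_reference <- function(tiles, kernel_px = 121) {
  if (length(tiles) < 1) stop("need at least one tile")
  if (length(tiles) == 1) {
    warning("building flat-field reference from a single tile")
  }
  shp <- dim(tiles[[1]])
  for (tl in tiles) {
    if (!identical(dim(tl), shp)) stop("shape error: tile shape mismatch")
  }
  avg <- Reduce(`+`, tiles) / length(tiles)
  sm <- .gaussian_blur(avg, sigma = kernel_px / 6, support = kernel_px)
  ref <- sm / mean(sm)
  if (any(ref <= 0)) stop("flat-field reference must be strictly positive")
  structure(list(image = ref, kernel_px = kernel_px),
            class = "flatfield_reference")
}

#' Divide a tile by the flat-field reference
#'
#' @param tile Image matrix.
#' @param reference A `flatfield_reference` (or a bare positive matrix of
#'   the same shape).
#' @return Corrected image, same shape and global intensity scale.
#' @export
apply_flatfield <- function(tile, reference) {
  ref <- if (inherits(reference, "flatfield_reference")) reference$image
         else reference
  if (!identical(dim(tile), dim(ref))) stop("shape error: shape mismatch")
  if (any(ref <= 0)) stop("reference must be strictly positive")
  tile / ref
}

#' Stitch tiles onto a known-layout grid
#'
#' Tiles are placed at the layout's origins; pixels covered by several
#' tiles are blended linearly with distance-to-edge weights, so exact
#' crops of a truth image reassemble it exactly.
#'
#' @param tiles List of tile matrices, row-major tile order.
#' @param layout A [mosaic_layout()] with `length(tiles)` origins.
#' @return The mosaic image (matrix of `layout$mosaic_shape`).
#' @export
stitch_grid <- function(tiles, layout) {
  if (length(tiles) != nrow(layout$origins)) {
    stop("parameter error: tile count does not match the layout")
  }
  th <- layout$tile_shape[1]; tw <- layout$tile_shape[2]
  for (tl in tiles) {
    if (!identical(dim(tl), c(th, tw))) stop("shape error: tile shape mismatch")
  }
  wgt <- outer(pmin(seq_len(th), rev(seq_len(th))),
               pmin(seq_len(tw), rev(seq_len(tw))))
  acc <- matrix(0, layout$mosaic_shape[1], layout$mosaic_shape[2])
  wsum <- matrix(0, layout$mosaic_shape[1], layout$mosaic_shape[2])
  for (i in seq_along(tiles)) {
    r <- layout$origins[i, 1] + seq_len(th)
    c <- layout$origins[i, 2] + seq_len(tw)
    acc[r, c] <- acc[r, c] + tiles[[i]] * wgt
    wsum[r, c] <- wsum[r, c] + wgt
  }
  out <- acc / wsum
  out[wsum == 0] <- 0
  out
}

#' Background-subtracted green/red ratio image
#'
#' `(green - bg_green) / (red - bg_red)` pixelwise; pixels whose
#' background-subtracted red is <= 0 are masked (`NA`), never infinite.
#' Background levels are mean fluorescence measured from wild-type slices.
#'
#' @param green,red Image matrices of identical shape.
#' @param bg_green,bg_red Scalar background levels (>= 0).
#' @return Ratio matrix with `NA` at masked pixels and attribute
#'   `n_masked`; warns when every pixel is masked.
#' @export
ratio_image <- function(green, red, bg_green = 0, bg_red = 0) {
  if (!identical(dim(green), dim(red))) stop("shape error: shape mismatch")
  stopifnot(bg_green >= 0, bg_red >= 0)
  den <- red - bg_red
  out <- (green - bg_green) / den
  bad <- den <= 0
  out[bad] <- NA_real_
  if (all(bad)) warning("degenerate input: all ratio pixels masked")
  attr(out, "n_masked") <- sum(bad)
  out
}

#' Background-subtracted green/red ratio trace
#'
#' @param green,red [trace()] objects on a common time base.
#' @param bg_green,bg_red Scalar background levels.
#' @return A ratio-stage [trace()]; samples with non-positive denominator
#'   are `NA` and counted in attribute `n_masked`.
#' @export
ratio_trace <- function(green, red, bg_green = 0, bg_red = 0) {
  if (length(green$values) != length(red$values) ||
      max(abs(green$times_s - red$times_s)) > 1e-9) {
    stop("shape error: traces do not share a time base")
  }
  den <- red$values - bg_red
  vals <- (green$values - bg_green) / den
  bad <- den <= 0
  vals[bad] <- NA_real_
  out <- trace(green$times_s, ifelse(is.na(vals), 0, vals), stage = "ratio",
               id = green$id)
  out$values[bad] <- NA_real_
  attr(out, "n_masked") <- sum(bad)
  out
}
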