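# Punctum detection by Laplace-operator SD thresholding, fixed 3x3 ROIs,
# neighboring background ROIs, and ROI trace extraction.

#' Segmentation parameters
#'
#' @param k_sd Threshold as a multiple of the SD of the Laplacian-filtered
#'   image (> 0).
#' @param min_area_px,max_area_px Connected-component size limits, pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(k_sd = 3, min_area_px = 2, max_area_px = 100,
                                connectivity = 8) {
  stopifnot(k_sd > 0, min_area_px >= 1, min_area_px <= max_area_px,
            connectivity %in% c(4, 8))
  structure(list(k_sd = k_sd, min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Pixelwise temporal average of a frame range
#'
#' @param stack A T x H x W array or a [two_channel_stack()] (green channel).
#' @param frame_range Integer interval `c(first, last)` (1-based frame
#'   indices); default all frames.
#' @return H x W matrix of per-pixel means.
#' @export
temporal_average <- function(stack, frame_range = NULL) {
  frames <- if (inherits(stack, "two_channel_stack")) stack$green else stack
  tn <- dim(frames)[1]
  if (is.null(frame_range)) frame_range <- c(1, tn)
  i0 <- frame_range[1]; i1 <- frame_range[length(frame_range)]
  if (i0 < 1 || i1 > tn || i1 < i0) {
    stop("parameter error: empty or out-of-range frame range")
  }
  sub <- frames[i0:i1, , , drop = FALSE]
  d <- dim(sub)
  matrix(colMeans(matrix(sub, d[1], d[2] * d[3])), d[2], d[3])
}

# Negated discrete Laplacian (kernel [[0,1,0],[1,-4,1],[0,1,0]], sign
# flipped so bright blobs give a positive response), replicate-padded at
# the borders.
.neg_laplacian <- function(img) {
  h <- nrow(img); w <- ncol(img)
  up <- img[c(1, 1:(h - 1)), , drop = FALSE]
  dn <- img[c(2:h, h), , drop = FALSE]
  lf <- img[, c(1, 1:(w - 1)), drop = FALSE]
  rt <- img[, c(2:w, w), drop = FALSE]
  4 * img - (up + dn + lf + rt)
}

# Label connected components of a logical mask. Returns an integer matrix
# (0 = background). Adjacency built explicitly and resolved with igraph.
.label_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)                      # column-major linear indices
  if (!length(idx)) return(matrix(0L, h, w))
  id_of <- integer(h * w)
  id_of[idx] <- seq_along(idx)
  rr <- (idx - 1) %% h
  cc <- (idx - 1) %/% h
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  edges <- NULL
  for (s in shifts) {
    nr <- rr + s[1]; nc <- cc + s[2]
    ok <- nr >= 0 & nr < h & nc >= 0 & nc < w
    nidx <- nc * h + nr + 1
    ok[ok] <- id_of[nidx[ok]] > 0
    if (any(ok)) {
      edges <- rbind(edges, cbind(id_of[idx[ok]], id_of[nidx[ok]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, h, w)
  lab[idx] <- as.integer(memb)
  lab
}

#' Detect punctate boutons in a temporally averaged image
#'
#' Pipeline: negated discrete Laplacian of the image, threshold at
#' `k_sd` times the SD of all Laplacian pixel values, connected components
#' at the requested connectivity, discard components outside
#' `[min_area_px, max_area_px]`, and emit one punctum ROI per surviving
#' component centered at its pixel of maximum image intensity (ties broken
#' toward the smallest row-major index). Output is sorted by center
#' (row, col). A constant image (SD = 0) yields no ROIs.
#'
#' @param avg_image H x W matrix (H, W >= 5), finite values.
#' @param params A [segmentation_params()].
#' @return List of punctum [roi()] objects.
#' @export
detect_puncta <- function(avg_image, params = segmentation_params()) {
  if (nrow(avg_image) < 5 || ncol(avg_image) < 5) {
    stop("image must be at least 5 x 5")
  }
  if (any(!is.finite(avg_image))) stop("image must be finite")
  resp <- .neg_laplacian(avg_image)
  sdv <- stats::sd(as.vector(resp))
  if (sdv == 0) return(list())
  mask <- resp > params$k_sd * sdv
  lab <- .label_components(mask, params$connectivity)
  n_comp <- max(lab)
  if (n_comp == 0) return(list())
  h <- nrow(avg_image)
  rois <- list()
  for (k in seq_len(n_comp)) {
    lin <- which(lab == k)
    if (length(lin) < params$min_area_px || length(lin) > params$max_area_px) {
      next
    }
    lin <- sort(lin)
    rows0 <- (lin - 1) %% h
    cols0 <- (lin - 1) %/% h
    vals <- avg_image[lin]
    # ties -> smallest row-major (row, col) index
    rm_idx <- rows0 * ncol(avg_image) + cols0
    best <- which(vals == max(vals))
    best <- best[which.min(rm_idx[best])]
    rois[[length(rois) + 1]] <-
      roi(id = "tmp", pixels = cbind(rows0, cols0),
          center = c(rows0[best], cols0[best]), kind = "punctum")
  }
  if (!length(rois)) return(list())
  ord <- order(vapply(rois, function(r) r$center[1], integer(1)),
               vapply(rois, function(r) r$center[2], integer(1)))
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]$id <- sprintf("p%03d", i)
  rois
}

#' Fixed 3x3 ROIs around given centers
#'
#' The 3x3 window that just circumscribes a single bouton, cropped at the
#' image borders.
#'
#' @param centers List (or n x 2 matrix) of 0-based (row, col) centers.
#' @param image_shape `c(H, W)`.
#' @return List of fixed3x3 [roi()] objects, one per center.
#' @export
make_fixed_rois <- function(centers, image_shape) {
  if (is.matrix(centers)) centers <- asplit(centers, 1)
  h <- image_shape[1]; w <- image_shape[2]
  lapply(seq_along(centers), function(i) {
    ctr <- as.integer(round(centers[[i]]))
    if (ctr[1] < 0 || ctr[1] >= h || ctr[2] < 0 || ctr[2] >= w) {
      stop("parameter error: center outside image")
    }
    rows <- max(0, ctr[1] - 1):min(h - 1, ctr[1] + 1)
    cols <- max(0, ctr[2] - 1):min(w - 1, ctr[2] + 1)
    px <- as.matrix(expand.grid(row = rows, col = cols))
    roi(id = sprintf("f%03d", i), pixels = px, center = ctr,
        kind = "fixed3x3")
  })
}

#' Pick neighboring background ROIs for a set of puncta
#'
#' For each punctum, a 3x3 background ROI is placed at `offset_px` from the
#' punctum center in the first of the 8 compass directions (base order N,
#' NE, E, SE, S, SW, W, NW, shuffled by `seed`) whose window lies in-image
#' and overlaps no punctum ROI. Puncta with no qualifying direction are
#' skipped and reported.
#'
#' @param puncta List of punctum [roi()] objects.
#' @param image_shape `c(H, W)`.
#' @param offset_px Center-to-center offset (>= 3).
#' @param seed Integer seed for the direction shuffle.
#' @return List of background [roi()] objects (named by source punctum id),
#'   with attribute `skipped` listing punctum ids that received none.
#' @export
pick_background_rois <- function(puncta, image_shape, offset_px = 4,
                                 seed = 1) {
  stopifnot(offset_px >= 3)
  h <- image_shape[1]; w <- image_shape[2]
  occupied <- matrix(FALSE, h, w)
  for (p in puncta) occupied[p$pixels[, 1] + 1 + p$pixels[, 2] * h] <- TRUE
  dirs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  out <- list()
  skipped <- character(0)
  .with_seed(seed, {
    ord <- sample(8)
    for (p in puncta) {
      placed <- FALSE
      for (d in dirs[ord]) {
        ctr <- p$center + as.integer(round(offset_px * d / sqrt(sum(d^2))))
        rows <- (ctr[1] - 1):(ctr[1] + 1)
        cols <- (ctr[2] - 1):(ctr[2] + 1)
        if (min(rows) < 0 || max(rows) >= h ||
            min(cols) < 0 || max(cols) >= w) next
        if (any(occupied[rows + 1, cols + 1])) next
        px <- as.matrix(expand.grid(row = rows, col = cols))
        out[[length(out) + 1]] <-
          roi(id = paste0("bg_", p$id), pixels = px, center = ctr,
              kind = "background")
        placed <- TRUE
        break
      }
      if (!placed) skipped <- c(skipped, p$id)
    }
  })
  attr(out, "skipped") <- skipped
  out
}

#' Extract mean-intensity traces for a set of ROIs
#'
#' Per ROI and frame, the arithmetic mean of the ROI's pixels. Output order
#' matches the input ROI order; traces are raw stage on the stack's time
#' base.
#'
#' @param stack A T x H x W array or a [two_channel_stack()] (green).
#' @param rois List of [roi()] objects.
#' @param frame_interval_s Seconds per frame (taken from the stack when a
#'   [two_channel_stack()] is given).
#' @return List of raw [trace()] objects.
#' @export
extract_traces <- function(stack, rois, frame_interval_s = NULL) {
  if (inherits(stack, "two_channel_stack")) {
    frame_interval_s <- stack$frame_interval_s
    frames <- stack$green
  } else {
    frames <- stack
    if (is.null(frame_interval_s)) frame_interval_s <- 1
  }
  d <- dim(frames)
  tn <- d[1]; h <- d[2]; w <- d[3]
  m <- matrix(frames, tn, h * w)          # column = pixel (col-major H x W)
  times <- (seq_len(tn) - 1) * frame_interval_s
  lapply(rois, function(r) {
    if (any(r$pixels[, 1] < 0 | r$pixels[, 1] >= h |
            r$pixels[, 2] < 0 | r$pixels[, 2] >= w)) {
      stop("shape error: ROI pixel outside frame geometry")
    }
    cols <- r$pixels[, 2] * h + r$pixels[, 1] + 1
    vals <- if (length(cols) == 1) m[, cols] else rowMeans(m[, cols])
    trace(times, vals, stage = "raw", id = r$id)
  })
}

#' Match detected puncta to true bouton centers
#'
#' Greedy nearest-pair matching within a radius; used to score segmentation
#' recall and precision against generator truth.
#'
#' @param detected List of [roi()] (centers used).
#' @param true_centers n x 2 matrix of true (row, col) centers.
#' @param radius_px Maximum matching distance.
#' @return `list(recall =, precision =, n_matched =)`.
#' @export
match_puncta <- function(detected, true_centers, radius_px = 2) {
  n_det <- length(detected)
  n_true <- nrow(true_centers)
  if (n_det == 0 || n_true == 0) {
    return(list(recall = 0, precision = if (n_det == 0) 1 else 0,
                n_matched = 0L))
  }
  det <- t(vapply(detected, function(r) as.numeric(r$center), numeric(2)))
  dmat <- sqrt(outer(det[, 1], true_centers[, 1], "-")^2 +
               outer(det[, 2], true_centers[, 2], "-")^2)
  matched <- 0L
  repeat {
    best <- which.min(dmat)
    if (!length(best) || dmat[best] > radius_px) break
    matched <- matched + 1L
    i <- (best - 1) %% n_det + 1
    j <- (best - 1) %/% n_det + 1
    dmat[i, ] <- Inf
    dmat[, j] <- Inf
    if (all(!is.finite(dmat))) break
  }
  list(recall = matched / n_true, precision = matched / n_det,
       n_matched = matched)
}
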