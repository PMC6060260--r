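# Responder / non-responder classification of normalized ROI traces by
# agglomerative clustering, plus mean traces and the sorted F/F0 raster.

# Stack a list of traces into an n x T matrix; error on mixed time bases.
.trace_matrix <- function(traces) {
  tb <- traces[[1]]$times_s
  for (tr in traces) {
    if (length(tr$times_s) != length(tb) ||
        max(abs(tr$times_s - tb)) > 1e-9) {
      stop("shape error: traces do not share a common time base")
    }
  }
  list(x = t(vapply(traces, function(tr) tr$values,
                    numeric(length(tb)))),
       times = tb)
}

#' Classify traces as responding or non-responding
#'
#' Each trace (z-scored over time) is a feature vector; agglomerative
#' clustering (Ward linkage, Euclidean distance) cut into two clusters
#' separates stimulus-locked traces from flat ones. The cluster with the
#' higher mean F/F0 inside `[onset, onset + window]` is the responder
#' candidate; if its mean trace's peak response (`max F/F0 - 1`) is below
#' `min_response` the set is declared all non-responding — the guard that
#' replaces the study's manual verification step.
#'
#' @param traces List of normalized [trace()] objects on a common time base.
#' @param stim_onset_s Stimulus onset on the (re-referenced) time base;
#'   normalized traces have their last pre-onset sample at 0.
#' @param stim_window_s Response window length after onset, seconds (> 0).
#' @param min_response Minimum mean peak response (F/F0 - 1) for the
#'   candidate cluster to count as responding. Default: 2x the pooled SD of
#'   pre-onset F/F0 values across traces.
#' @return `list(labels =, proportion =, mean_responder =,
#'   mean_nonresponder =, n_total =, min_response =)`; `proportion` is
#'   exactly `sum(labels) / n_total`, and `mean_responder` is `NULL` when
#'   there are no responders.
#' @export
classify_responders <- function(traces, stim_onset_s = 0, stim_window_s = 2,
                                min_response = NULL) {
  stopifnot(stim_window_s > 0, length(traces) >= 1)
  for (tr in traces) {
    if (tr$stage != "normalized") stop("all traces must be normalized stage")
  }
  tm <- .trace_matrix(traces)
  x <- tm$x; times <- tm$times
  n <- nrow(x)
  pre <- times <= stim_onset_s
  if (is.null(min_response)) {
    min_response <- 2 * stats::sd(as.vector(x[, pre, drop = FALSE]) - 1)
  }
  win <- times > stim_onset_s & times <= stim_onset_s + stim_window_s
  if (!any(win)) stop("protocol error: no samples in the response window")

  if (n < 2) {
    labels <- (max(x[1, win]) - 1) >= min_response
  } else {
    z <- t(apply(x, 1, function(v) {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    }))
    cl <- stats::cutree(stats::hclust(stats::dist(z), method = "ward.D2"),
                        k = 2)
    win_mean <- tapply(rowMeans(x[, win, drop = FALSE]), cl, mean)
    cand <- as.integer(names(which.max(win_mean)))
    labels <- cl == cand
    cand_mean <- colMeans(x[labels, , drop = FALSE])
    if (max(cand_mean[win]) - 1 < min_response) labels[] <- FALSE
  }
  mean_resp <- if (any(labels)) mean_trace(traces, labels) else NULL
  mean_non <- if (any(!labels)) mean_trace(traces, !labels) else NULL
  list(labels = labels, proportion = sum(labels) / n,
       mean_responder = mean_resp, mean_nonresponder = mean_non,
       n_total = n, min_response = min_response)
}

#' Pointwise mean of a masked subset of traces
#'
#' @param traces List of [trace()] on a common time base.
#' @param mask Logical vector selecting the subset (default all).
#' @return A [trace()] of the pointwise mean, at the common stage.
#' @export
mean_trace <- function(traces, mask = rep(TRUE, length(traces))) {
  sel <- traces[mask]
  if (!length(sel)) stop("empty-selection error: no traces selected")
  tm <- .trace_matrix(sel)
  stage <- sel[[1]]$stage
  trace(tm$times, colMeans(tm$x), stage = stage,
        f0 = if (stage == "normalized") 1 else NULL, id = "mean")
}

#' Build an ROI x time raster matrix from normalized traces
#'
#' Row i holds trace i's values; rows are ordered (descending, stable) by
#' the requested statistic. `"peak"` sorts by each trace's maximum;
#' `"onset_amplitude"` by the mean of the first three post-onset samples;
#' `"none"` keeps input order.
#'
#' @param traces List of normalized [trace()] on a common time base.
#' @param sort_by `"peak"`, `"onset_amplitude"` or `"none"`.
#' @param stim_onset_s Onset used by `"onset_amplitude"`.
#' @return n x T numeric matrix with attribute `times_s`.
#' @export
build_raster <- function(traces, sort_by = c("none", "peak",
                                             "onset_amplitude"),
                         stim_onset_s = 0) {
  sort_by <- match.arg(sort_by)
  tm <- .trace_matrix(traces)
  x <- tm$x
  if (sort_by != "none") {
    key <- switch(sort_by,
      peak = apply(x, 1, max),
      onset_amplitude = {
        post <- which(tm$times > stim_onset_s)
        idx <- post[seq_len(min(3, length(post)))]
        rowMeans(x[, idx, drop = FALSE])
      })
    x <- x[order(-key), , drop = FALSE]
  }
  attr(x, "times_s") <- tm$times
  x
}
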