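# Line-profile Pearson colocalization.

#' Paired intensity line profile
#'
#' Intensities of two channels sampled along the same line through a
#' double-stained section.
#'
#' @param distance Positions along the line (pixels or micrometers).
#' @param a,b Intensities of channels 1 and 2 (equal lengths >= 3, finite).
#' @return An object of class `profile_pair`.
#' @export
profile_pair <- function(distance, a, b) {
  stopifnot(length(a) == length(b), length(distance) == length(a),
            length(a) >= 3)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("profile intensities must be finite")
  }
  structure(list(distance = as.numeric(distance), a = as.numeric(a),
                 b = as.numeric(b)),
            class = "profile_pair")
}

#' Pearson colocalization of a line-profile pair
#'
#' Sample Pearson correlation of the two channels' co-variation along the
#' line, with a two-sided p value from the t distribution on n - 2 degrees
#' of freedom.
#'
#' @param pair A [profile_pair()].
#' @return `list(r =, p =, n =)`.
#' @export
pearson_profile <- function(pair) {
  if (stats::sd(pair$a) == 0 || stats::sd(pair$b) == 0) {
    stop("degenerate input: zero variance in a profile channel")
  }
  ct <- stats::cor.test(pair$a, pair$b, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(pair$a))
}
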