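#' Point of stability of an accuracy-difference curve
#'
#' Corridor scan for sample-size planning: the point of stability is the
#' smallest grid sample size after which the difference curve stays inside
#' the corridor `[-half_width, +half_width]` for every larger grid value.
#' Differences exactly on the boundary count as inside.  If the final grid
#' point lies outside the corridor, stability is never reached and `pos_n`
#' is `NA`.
#'
#' @param curve A difference-curve tibble (e.g. from [run_study2()]) with
#'   columns `n` and `mean_diff`, and optionally `scheme`; the scan is
#'   applied per scheme.
#' @param half_width Corridor half-width on the accuracy-difference scale,
#'   `> 0`.  Default 0.05 (five percentage points).
#' @return A tibble with one row per scheme: `scheme`, `pos_n` (`NA` when
#'   not reached), `reached`, `half_width`.
#' @examples
#' curve <- tibble::tibble(n = c(40, 50, 60, 70, 80),
#'                         mean_diff = c(0.30, 0.20, 0.06, 0.04, 0.03))
#' point_of_stability(curve)  # pos_n = 70
#' @export
point_of_stability <- function(curve, half_width = 0.05) {
  check_difference_curve(curve)
  check_half_width(half_width)
  grouped <- dplyr::group_by(ensure_scheme(curve), .data$scheme)
  out <- dplyr::summarise(grouped,
    pos_n = scan_pos_n(.data$n, .data$mean_diff, half_width),
    .groups = "drop")
  dplyr::mutate(out,
    reached = !is.na(.data$pos_n),
    half_width = half_width)
}

# Smallest grid n such that |diff| <= half_width for all grid n' >= n.
scan_pos_n <- function(n, diff, half_width) {
  ord <- order(n)
  n <- n[ord]
  diff <- diff[ord]
  inside <- abs(diff) <= half_width
  # a point is stable iff it and every later point are inside
  stable <- rev(cumprod(rev(inside))) > 0
  if (!any(stable)) return(NA_integer_)
  as.integer(n[which(stable)[1L]])
}

#' Grid points outside the stability corridor
#'
#' Diagnostic companion of [point_of_stability()]: lists every grid point
#' whose mean difference lies strictly outside `[-half_width,
#' +half_width]`.  The list is empty exactly when the point of stability
#' is the first grid value.
#'
#' @inheritParams point_of_stability
#' @return A tibble with columns `scheme`, `n`, `mean_diff`, one row per
#'   exceedance, ordered by `n` within scheme.
#' @export
corridor_exceedances <- function(curve, half_width = 0.05) {
  check_difference_curve(curve)
  check_half_width(half_width)
  out <- dplyr::filter(ensure_scheme(curve),
                       abs(.data$mean_diff) > half_width)
  out <- dplyr::arrange(out, .data$scheme, .data$n)
  dplyr::select(out, "scheme", "n", "mean_diff")
}

check_difference_curve <- function(curve) {
  if (!is.data.frame(curve) || nrow(curve) == 0L) {
    stop("`curve` must be a non-empty difference-curve data frame.",
         call. = FALSE)
  }
  if (!all(c("n", "mean_diff") %in% names(curve))) {
    stop("`curve` must have columns `n` and `mean_diff`.", call. = FALSE)
  }
  invisible(curve)
}

check_half_width <- function(half_width) {
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      is.na(half_width) || half_width <= 0) {
    stop("`half_width` must be a single positive number.", call. = FALSE)
  }
  invisible(half_width)
}

ensure_scheme <- function(curve) {
  if (!"scheme" %in% names(curve)) {
    curve <- dplyr::mutate(curve, scheme = "difference")
  }
  curve
}
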