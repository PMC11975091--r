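#' Full geometric measurement of one specimen at one time state
#'
#' Runs the geometry chain — spline fit, equidistant resampling, curvature
#' profile, boundary length, opening angle — for the inner and outer
#' boundary traces of a single specimen image.
#'
#' @param inner,outer [boundary_trace()] objects for the two borders; both
#'   must share the closed flag (a ring is uncut on both borders).
#' @param degree,smoothing passed to [fit_boundary_spline()].
#' @param n number of equidistant resampling points (default 40).
#' @param time_state optional label stored with the result.
#' @return object of class `segment_geometry`: per-border lists
#'   (`resampled`, `curvature`, `length_mm`) plus `opening_angle_deg`
#'   (`NA` for uncut rings) and `time_state`.
#' @export
segment_geometry <- function(inner, outer, degree = 3L, smoothing = 0,
                             n = 40L, time_state = NA_character_) {
  stopifnot(inherits(inner, "boundary_trace"),
            inherits(outer, "boundary_trace"))
  if (inner$border != "inner" || outer$border != "outer") {
    stop("pass the inner trace first and the outer trace second")
  }
  if (!identical(inner$closed, outer$closed)) {
    stop("inner and outer traces disagree on the closed flag")
  }
  measure <- function(tr) {
    cv <- fit_boundary_spline(tr, degree = degree, smoothing = smoothing)
    rb <- resample_equidistant(cv, n)
    list(resampled = rb,
         curvature = local_curvature(cv, rb),
         length_mm = rb$polyline_length)
  }
  gi <- measure(inner)
  go <- measure(outer)
  if (gi$length_mm >= go$length_mm) {
    warning("inner boundary is not shorter than outer boundary (",
            sprintf("%.3f >= %.3f mm", gi$length_mm, go$length_mm),
            "); traces may cross")
  }
  phi <- if (inner$closed) NA_real_ else opening_angle(gi$resampled)
  structure(list(inner = gi, outer = go, opening_angle_deg = phi,
                 closed = inner$closed, time_state = time_state),
            class = "segment_geometry")
}

#' @export
print.segment_geometry <- function(x, ...) {
  cat("<segment_geometry>",
      if (!is.na(x$time_state)) paste0("[", x$time_state, "]"), "\n")
  cat(sprintf("  inner: kappa %.4f 1/mm, length %.3f mm\n",
              x$inner$curvature$mean_kappa, x$inner$length_mm))
  cat(sprintf("  outer: kappa %.4f 1/mm, length %.3f mm\n",
              x$outer$curvature$mean_kappa, x$outer$length_mm))
  cat(if (x$closed) "  opening angle: - (uncut ring)\n"
      else sprintf("  opening angle: %.2f deg\n", x$opening_angle_deg))
  invisible(x)
}
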