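#' Mean wall thickness from dial-indicator readings
#'
#' Specimen thickness is measured with a dial indicator at three locations;
#' the arithmetic mean is used in all downstream analysis.
#'
#' @param readings numeric vector of exactly 3 positive thickness readings
#'   (mm).
#' @return mean thickness in mm.
#' @export
mean_thickness <- function(readings) {
  if (!is.numeric(readings) || length(readings) != 3L) {
    stop("exactly 3 thickness readings are required")
  }
  if (anyNA(readings) || any(!is.finite(readings)) || any(readings <= 0)) {
    stop("thickness readings must all be positive and non-missing")
  }
  mean(readings)
}

#' Adventitia thickness percentage (A%)
#'
#' The ratio of the adventitia thickness to the summed thickness of the
#' adventitia and media-intima layers. Because some media always remains
#' attached to the peeled adventitia, A% serves as a proxy for separation
#' quality: higher values indicate more residual media on the adventitia.
#'
#' @param t_adv adventitia thickness, mm.
#' @param t_mi media-intima thickness, mm.
#' @return A% as a fraction in (0, 1).
#' @examples
#' adventitia_percentage(0.36, 0.60) # 0.375 -> 0.38 to two decimals
#' adventitia_percentage(0.47, 0.70) # 0.402 -> 0.40
#' @export
adventitia_percentage <- function(t_adv, t_mi) {
  if (!is.numeric(t_adv) || !is.numeric(t_mi) ||
      anyNA(c(t_adv, t_mi)) || any(c(t_adv, t_mi) <= 0)) {
    stop("both thicknesses must be positive")
  }
  t_adv / (t_adv + t_mi)
}

#' Circumferential boundary strain between two time states
#'
#' Percent length change of one boundary relative to the uncut-ring length
#' of the same specimen: `100 * (L_final - L_ref) / L_ref`. Positive values
#' mean elongation.
#'
#' @param l_ref boundary length in the reference (uncut ring) state, mm.
#' @param l_final boundary length in the final state, mm.
#' @param boundary `"inner"` or `"outer"`.
#' @param specimen_id optional id carried through; when both states carry an
#'   id they must match (strains are paired within a physical specimen).
#' @param reference_state,final_state optional state labels.
#' @return object of class `strain_result` with `strain_pct` and labels.
#' @export
boundary_strain <- function(l_ref, l_final, boundary = c("inner", "outer"),
                            specimen_id = NULL,
                            reference_state = "ring", final_state = "final") {
  boundary <- match.arg(boundary)
  if (!is.numeric(l_ref) || !is.numeric(l_final) ||
      l_ref <= 0 || l_final <= 0) {
    stop("lengths must be positive")
  }
  if (is.list(specimen_id) && length(specimen_id) == 2L &&
      !identical(specimen_id[[1L]], specimen_id[[2L]])) {
    stop("strain reference and final state belong to different specimens: ",
         specimen_id[[1L]], " vs ", specimen_id[[2L]])
  }
  structure(list(strain_pct = 100 * (l_final - l_ref) / l_ref,
                 boundary = boundary,
                 specimen_id = if (is.list(specimen_id)) specimen_id[[1L]]
                               else specimen_id,
                 reference_state = reference_state,
                 final_state = final_state),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf("<strain_result> %s boundary %s -> %s: %+.2f%%\n",
              x$boundary, x$reference_state, x$final_state, x$strain_pct))
  invisible(x)
}

#' Membrane / bending decomposition of boundary strains
#'
#' Splits the inner and outer circumferential strains of a specimen into a
#' through-thickness-uniform (membrane) component and an antisymmetric
#' (bending) component, assuming linear strain variation across the wall:
#' membrane = (inner + outer)/2, bending = (inner - outer)/2. The media
#' deforms mostly by bending; the adventitia shows both bending and a
#' roughly uniform contraction.
#'
#' @param inner_pct,outer_pct boundary strains in percent, from
#'   [boundary_strain()] or numeric.
#' @return object of class `strain_decomposition` with `membrane_pct` and
#'   `bending_pct`; inner = membrane + bending, outer = membrane - bending.
#' @examples
#' strain_decomposition(6, -6)       # pure bending
#' strain_decomposition(-3.80, -3.81) # nearly pure membrane contraction
#' @export
strain_decomposition <- function(inner_pct, outer_pct) {
  if (inherits(inner_pct, "strain_result")) inner_pct <- inner_pct$strain_pct
  if (inherits(outer_pct, "strain_result")) outer_pct <- outer_pct$strain_pct
  stopifnot(is.numeric(inner_pct), is.numeric(outer_pct))
  structure(list(membrane_pct = (inner_pct + outer_pct) / 2,
                 bending_pct = (inner_pct - outer_pct) / 2),
            class = "strain_decomposition")
}

#' @export
print.strain_decomposition <- function(x, ...) {
  cat(sprintf("<strain_decomposition> membrane %+.3f%%, bending %+.3f%%\n",
              x$membrane_pct, x$bending_pct))
  invisible(x)
}
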