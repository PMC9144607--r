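## Unit conventions, centralized.
##
## Mechanics (forces, accelerations, velocities, viscosity, diffusivity) are
## SI: m, s, kg.  Geometry on the parcel grid (positions, parcel sizes, cell
## radii) is in micrometres, and metabolite concentrations are in
## cell equivalents per cubic micrometre, the scale on which all biological
## quantities are reported.  Every conversion goes through the constants
## below; no literal 1e-6 appears elsewhere.

#' Unit conversion helpers
#'
#' Lengths on the parcel grid are micrometres; mechanical quantities are SI.
#' These helpers are the only place the two meet.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

## metres per micrometre
.M_PER_UM <- 1e-6

#' @rdname units
#' @export
um_to_m <- function(x) x * .M_PER_UM

#' @rdname units
#' @export
m_to_um <- function(x) x / .M_PER_UM

#' @rdname units
#' @export
min_to_s <- function(x) x * 60

#' @rdname units
#' @export
s_to_min <- function(x) x / 60

#' @rdname units
#' @export
cm2s_to_m2s <- function(x) x * 1e-4

#' @rdname units
#' @export
rpm_to_rad_s <- function(x) x * 2 * pi / 60
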