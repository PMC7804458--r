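#' Drag-measurement conditions
#'
#' Physical conditions for one viscous-drag measurement of a sphere
#' translating parallel to a nearby wall: dynamic viscosity of the medium,
#' bead radius, distance from the sphere centre to the surface, and the
#' relative fluid--bead speed.
#'
#' @param viscosity Dynamic viscosity (Pa s), > 0.
#' @param radius Bead radius (m), > 0.
#' @param height Sphere-centre-to-wall distance (m); must exceed `radius`.
#'   There is no silent unbounded-fluid default: the wall distance is an
#'   explicit experimental parameter.
#' @param speed Relative fluid--bead speed (m/s); may be signed (stage
#'   direction).
#' @return An object of class `drag_conditions`.
#' @export
drag_conditions <- function(viscosity, radius, height, speed = 0) {
  assert_number(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  assert_number(radius, "radius", lower = 0, strict_lower = TRUE)
  assert_number(height, "height")
  if (height <= radius)
    tz_domain_error("height must exceed radius: the sphere cannot intersect the wall")
  assert_number(speed, "speed")
  structure(list(viscosity = viscosity, radius = radius, height = height,
                 speed = speed),
            class = "drag_conditions")
}

#' Faxen wall-correction factor for Stokes drag
#'
#' Multiplicative increase of the drag coefficient of a sphere of radius `r`
#' translating parallel to a plane wall at centre distance `h`:
#'
#' \deqn{f(r/h) = \left[1 - \tfrac{9}{16}\tfrac{r}{h}
#'   + \tfrac{1}{8}\left(\tfrac{r}{h}\right)^3
#'   + \tfrac{45}{256}\left(\tfrac{r}{h}\right)^4
#'   - \tfrac{1}{16}\left(\tfrac{r}{h}\right)^5\right]^{-1}}
#'
#' The factor is >= 1 and tends to 1 as `h` grows; a sphere whose surface is
#' five radii from the wall (`h = 6r`) experiences about a 10% drag
#' increase.
#'
#' @param radius Bead radius (m).
#' @param height Centre-to-wall distance (m), > `radius`.
#' @return Dimensionless correction factor >= 1.
#' @examples
#' faxen_factor(7.5e-6, 6 * 7.5e-6)  # ~1.10
#' @export
faxen_factor <- function(radius, height) {
  assert_number(radius, "radius", lower = 0, strict_lower = TRUE)
  assert_number(height, "height")
  if (height <= radius)
    tz_domain_error("height must exceed radius for the Faxen correction")
  x <- radius / height
  den <- 1 - (9 / 16) * x + (1 / 8) * x^3 + (45 / 256) * x^4 - (1 / 16) * x^5
  1 / den
}

#' Wall-corrected Stokes drag force
#'
#' Drag force on a sphere moving at `speed` relative to the fluid near a
#' wall: free Stokes drag `6 pi mu v r` multiplied by [faxen_factor()].
#' The sign follows the sign of the speed.
#'
#' @param cond A [drag_conditions()] object.
#' @return Force (N).
#' @export
drag_force <- function(cond) {
  stopifnot(inherits(cond, "drag_conditions"))
  6 * pi * cond$viscosity * cond$speed * cond$radius *
    faxen_factor(cond$radius, cond$height)
}
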