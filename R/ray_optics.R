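#' Optical medium pair for a single ray--sphere interaction
#'
#' Bundles the refractive indices of the immersion medium and of the trapped
#' sphere together with the trapping-laser wavelength. Used by the
#' geometric-optics force computation and by the regime check.
#'
#' @param n_medium Refractive index of the surrounding medium (>= 1).
#' @param n_sphere Refractive index of the sphere (>= 1).
#' @param wavelength Laser wavelength in metres (default 1064 nm, the
#'   Nd:YAG line typical of optical tweezers).
#' @return An object of class `optical_medium`.
#' @examples
#' optical_medium(1.33, 1.45)
#' @export
optical_medium <- function(n_medium, n_sphere, wavelength = 1064e-9) {
  assert_number(n_medium, "n_medium", lower = 1)
  assert_number(n_sphere, "n_sphere", lower = 1)
  assert_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  structure(list(n_medium = n_medium, n_sphere = n_sphere,
                 wavelength = wavelength),
            class = "optical_medium")
}

#' Snell refraction angle
#'
#' Refraction angle of a ray entering the sphere, from
#' `n_medium * sin(theta) = n_sphere * sin(r)`.
#'
#' @param theta Incidence angle in radians, in `[0, pi/2)`.
#' @param media An [optical_medium()].
#' @return Refraction angle in radians.
#' @export
snell_refraction <- function(theta, media) {
  stopifnot(inherits(media, "optical_medium"))
  assert_number(theta, "theta", lower = 0, upper = pi / 2, strict_upper = TRUE)
  s <- media$n_medium * sin(theta) / media$n_sphere
  if (s > 1)
    tz_domain_error("total internal reflection: n_medium*sin(theta) > n_sphere")
  asin(s)
}

#' Fresnel power coefficients at the sphere surface
#'
#' Power reflectance R and transmittance T for a ray crossing the
#' medium--sphere interface. The unpolarized value (the default, since
#' trapping-laser polarization is rarely tracked in this calibration) is the
#' mean of the s and p power reflectances. The index form of the Fresnel
#' formulas is used so that normal incidence is well defined.
#'
#' @param theta Incidence angle (rad).
#' @param media An [optical_medium()].
#' @param polarization One of `"unpolarized"`, `"s"`, `"p"`.
#' @param r_angle Optional refraction angle; computed via
#'   [snell_refraction()] when missing, cross-checked against Snell's law
#'   when supplied.
#' @return A list with elements `R` and `T` (`R + T = 1`).
#' @export
fresnel_coefficients <- function(theta, media,
                                 polarization = c("unpolarized", "s", "p"),
                                 r_angle = NULL) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(media, "optical_medium"))
  r <- snell_refraction(theta, media)
  if (!is.null(r_angle) && abs(r_angle - r) > 1e-8)
    tz_domain_error("supplied r_angle is inconsistent with Snell's law")
  n1 <- media$n_medium
  n2 <- media$n_sphere
  Rs <- ((n1 * cos(theta) - n2 * cos(r)) / (n1 * cos(theta) + n2 * cos(r)))^2
  Rp <- ((n1 * cos(r) - n2 * cos(theta)) / (n1 * cos(r) + n2 * cos(theta)))^2
  R <- switch(polarization, s = Rs, p = Rp, unpolarized = (Rs + Rp) / 2)
  list(R = R, T = 1 - R)
}

#' Ray geometry for one ray--sphere interaction
#'
#' Convenience constructor combining Snell refraction and Fresnel
#' coefficients into the geometry record consumed by [trap_forces()].
#'
#' @inheritParams fresnel_coefficients
#' @return An object of class `ray_geometry` with fields `theta`, `r_angle`,
#'   `R`, `T`.
#' @export
ray_geometry <- function(theta, media,
                         polarization = c("unpolarized", "s", "p")) {
  polarization <- match.arg(polarization)
  r <- snell_refraction(theta, media)
  fr <- fresnel_coefficients(theta, media, polarization)
  structure(list(theta = theta, r_angle = r, R = fr$R, T = fr$T,
                 polarization = polarization),
            class = "ray_geometry")
}

#' Geometric-optics trapping forces of a single refracted ray
#'
#' Forces exerted on a dielectric sphere by one ray of power `P`, in the
#' ray-optics regime (sphere much larger than the wavelength). `F_Z` is the
#' component reported parallel to the beam propagation vector and `F_X` the
#' orthogonal component; both are linear in the laser power:
#'
#' \deqn{F_Z = \frac{nP}{c}\left\{R\sin 2\theta -
#'   \frac{T^2[\sin(2\theta-2r) + R\sin 2\theta]}{1+R^2+2R\cos 2r}\right\}}
#' \deqn{F_X = \frac{nP}{c}\left\{1 + R\cos 2\theta -
#'   \frac{T^2[\cos(2\theta-2r) + R\cos 2\theta]}{1+R^2+2R\cos 2r}\right\}}
#'
#' Here `theta` is the incidence angle and `r` the refraction angle; the
#' closed forms are the geometric sums over the first reflected ray and the
#' infinite family of internally reflected transmitted rays. The
#' dimensionless trapping efficiencies `Q = F c / (n P)` are bounded by 2 in
#' magnitude (momentum transfer cannot exceed twice the photon momentum
#' flux); values outside that bound trigger a warning, not an error.
#'
#' @param P Laser power in watts (>= 0).
#' @param media An [optical_medium()].
#' @param ray A [ray_geometry()] (fields `theta`, `r_angle`, `R`, `T` with
#'   `R + T = 1`).
#' @return An object of class `optical_force` with fields `F_Z`, `F_X`
#'   (newtons) and `Q_Z`, `Q_X` (dimensionless).
#' @export
trap_forces <- function(P, media, ray) {
  assert_number(P, "P", lower = 0)
  stopifnot(inherits(media, "optical_medium"))
  if (abs(ray$R + ray$T - 1) > 1e-9)
    tz_domain_error("ray geometry inconsistent: R + T != 1")
  c0 <- 299792458
  th <- ray$theta
  r <- ray$r_angle
  R <- ray$R
  Tt <- ray$T
  den <- 1 + R^2 + 2 * R * cos(2 * r)
  Q_Z <- R * sin(2 * th) -
    Tt^2 * (sin(2 * th - 2 * r) + R * sin(2 * th)) / den
  Q_X <- 1 + R * cos(2 * th) -
    Tt^2 * (cos(2 * th - 2 * r) + R * cos(2 * th)) / den
  if (max(abs(Q_Z), abs(Q_X)) > 2)
    warning("trapping efficiency |Q| exceeds 2; ray geometry is unphysical")
  scale <- media$n_medium * P / c0
  structure(list(F_Z = scale * Q_Z, F_X = scale * Q_X,
                 Q_Z = Q_Z, Q_X = Q_X),
            class = "optical_force")
}

#' Check the geometric-optics regime
#'
#' The ray-optics force model is accurate when the sphere diameter exceeds
#' ten times the laser wavelength (strictly). Returns `FALSE` (with a
#' warning from callers, not an error) otherwise.
#'
#' @param bead_diameter Sphere diameter (m).
#' @param wavelength Laser wavelength (m).
#' @return Logical scalar.
#' @examples
#' regime_check(30e-6, 1064e-9)  # TRUE for a 30 um bead at 1064 nm
#' @export
regime_check <- function(bead_diameter, wavelength) {
  assert_number(bead_diameter, "bead_diameter", lower = 0, strict_lower = TRUE)
  assert_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  bead_diameter / wavelength > 10
}

#' Tilt correction of an applied force
#'
#' Projects a force onto the normal of the cantilever surface: when the
#' cantilever is not perpendicular to the applied optical force, the
#' effective force is `F * cos(alpha)` where `alpha` is the angle between
#' the force and the surface normal.
#'
#' @param F Force (N).
#' @param alpha Tilt angle (rad), in `[0, pi/2)`.
#' @return Corrected force (N).
#' @export
cosine_correction <- function(F, alpha) {
  assert_number(alpha, "alpha", lower = 0, upper = pi / 2,
                strict_upper = TRUE)
  F * cos(alpha)
}
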