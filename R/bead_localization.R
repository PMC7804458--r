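#' Bright-field bead image
#'
#' A grayscale raster of the colloidal bead with its physical pixel size.
#' Coordinate convention: the image row index is the microscope Z axis (the
#' direction the optical force displaces the probe), the column index is Y;
#' coordinates are 0-based with the origin at the centre of the top-left
#' pixel, y increasing rightwards and z downwards. The beam axis
#' (microscope X) is normal to the image, so all trackable motion is in
#' (Y, Z).
#'
#' @param pixels Numeric matrix of intensities (rows = z, cols = y), at
#'   least 64 x 64.
#' @param pixel_size Physical size of one pixel (m/px), > 0.
#' @return An object of class `bead_image`.
#' @export
bead_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    tz_domain_error("pixels must be a numeric matrix")
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    tz_domain_error("bead images must be at least 64 x 64 px")
  assert_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "bead_image")
}

#' Binarize a bead image
#'
#' Thresholds the image into a foreground mask of the bead disk. The bead
#' appears dark on the bright field, so by default pixels below the
#' threshold are foreground (`polarity = "dark"`). The threshold is either
#' Otsu's (computed on the intensity histogram) or a fixed value. Only the
#' largest connected foreground component is retained and its interior
#' holes are filled.
#'
#' @param image A [bead_image()] or plain numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Intensity threshold, required for `method = "fixed"`.
#' @param polarity `"dark"` (bead darker than threshold, default) or
#'   `"bright"`.
#' @return Binary (0/1) integer matrix of the same dimensions.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("dark", "bright")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- if (inherits(image, "bead_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px))
    tz_domain_error("image must be a numeric matrix or bead_image")
  rng <- range(px)
  if (method == "otsu") {
    if (diff(rng) == 0)
      tz_degenerate_error("constant image: Otsu threshold undefined")
    threshold <- EBImage::otsu(EBImage::Image(px), range = rng)
  } else {
    if (is.null(threshold))
      tz_domain_error("method = 'fixed' requires a threshold")
    assert_number(threshold, "threshold")
  }
  mask <- if (polarity == "dark") px < threshold else px > threshold
  if (!any(mask))
    tz_degenerate_error("empty foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  counts <- table(lab[lab > 0])
  keep <- as.integer(names(counts)[which.max(counts)])
  mask <- EBImage::fillHull(EBImage::Image((lab == keep) * 1))
  out <- matrix(as.integer(EBImage::imageData(mask) > 0.5),
                nrow = nrow(px), ncol = ncol(px))
  out
}

#' Sub-pixel boundary of a binary mask
#'
#' Extracts the 0.5-level contour of the mask (linear interpolation between
#' pixel centres) and returns the outer boundary as ordered (y, z)
#' coordinates in pixels. When the mask has holes (annulus), the contour
#' enclosing the largest area is selected.
#'
#' @param mask Binary matrix from [binarize()].
#' @return Data frame with numeric columns `y`, `z` (0-based px).
#' @export
edge_points <- function(mask) {
  if (!is.matrix(mask)) tz_domain_error("mask must be a matrix")
  z <- matrix(as.numeric(mask > 0), nrow = nrow(mask))
  cl <- grDevices::contourLines(x = 0:(nrow(z) - 1), y = 0:(ncol(z) - 1),
                                z = z, levels = 0.5)
  if (length(cl) == 0)
    tz_degenerate_error("mask has no boundary at the 0.5 level")
  shoelace <- function(cc) {
    xx <- cc$x; yy <- cc$y
    abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
  }
  best <- cl[[which.max(vapply(cl, shoelace, numeric(1)))]]
  # contourLines' x runs over rows (our z), y over columns (our y)
  pts <- data.frame(y = best$y, z = best$x)
  if (nrow(pts) < 8)
    tz_degenerate_error("foreground too small to define a boundary")
  pts
}

#' Circumcenter of three points
#'
#' The centre of the circle through three non-collinear boundary points:
#' the intersection of the perpendicular bisectors of the triangle sides,
#' computed in closed form. This is the elementary construction behind the
#' bead-centre determination: draw a triangle on the bead's edge and
#' intersect the side normals.
#'
#' @param A,B,C Numeric length-2 vectors `(y, z)`.
#' @param area_tol Minimum triangle area (px^2) below which the triple is
#'   rejected as collinear (default 1e-9).
#' @return Numeric `c(y, z)` of the centre; the circumradius is attached as
#'   attribute `"radius"`.
#' @export
circumcenter <- function(A, B, C, area_tol = 1e-9) {
  A <- as.numeric(A); B <- as.numeric(B); C <- as.numeric(C)
  d <- 2 * (A[1] * (B[2] - C[2]) + B[1] * (C[2] - A[2]) + C[1] * (A[2] - B[2]))
  if (abs(d) / 4 < area_tol)
    tz_degenerate_error("collinear triple: circumcenter undefined")
  a2 <- sum(A^2); b2 <- sum(B^2); c2 <- sum(C^2)
  uy <- (a2 * (B[2] - C[2]) + b2 * (C[2] - A[2]) + c2 * (A[2] - B[2])) / d
  uz <- (a2 * (C[1] - B[1]) + b2 * (A[1] - C[1]) + c2 * (B[1] - A[1])) / d
  out <- c(y = uy, z = uz)
  attr(out, "radius") <- sqrt(sum((A - out)^2))
  out
}

#' Robust bead-centre estimate from boundary points
#'
#' Two strategies:
#' * `"lsq_circle"` (default, deterministic): algebraic least-squares circle
#'   fit (Kasa), solved on mean-centred coordinates so the estimate is
#'   exactly translation-equivariant.
#' * `"triples_mean"`: the mean of the circumcenters of `n_triples` randomly
#'   drawn non-degenerate point triples — the averaging fallback recommended
#'   for not-perfectly-spherical particles; requires a `seed`. Triples are
#'   drawn with one vertex from each third of the (contour-ordered) point
#'   list: circumcenters of thin triangles amplify boundary noise without
#'   bound, so spreading the vertices around the periphery keeps the
#'   per-triple error comparable to the boundary noise itself.
#'
#' @param points Data frame with columns `y`, `z` (from [edge_points()]),
#'   >= 3 rows.
#' @param strategy `"lsq_circle"` or `"triples_mean"`.
#' @param n_triples Number of random triples for `"triples_mean"`.
#' @param seed RNG seed, mandatory for `"triples_mean"`.
#' @return An object of class `circle_estimate`: `center_y`, `center_z`,
#'   `radius`, `rms_residual` (all px), `n_points`.
#' @export
robust_center <- function(points, strategy = c("lsq_circle", "triples_mean"),
                          n_triples = 500, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.data.frame(points) || !all(c("y", "z") %in% names(points)))
    tz_domain_error("points must be a data frame with columns y, z")
  n <- nrow(points)
  if (n < 3)
    tz_insufficient_data("at least 3 boundary points are required")
  y <- points$y; z <- points$z
  if (strategy == "lsq_circle") {
    my <- mean(y); mz <- mean(z)
    u <- y - my; v <- z - mz
    # Kasa fit: minimize sum (u^2+v^2 + D u + E v + F)^2, linear in (D,E,F);
    # computed on mean-centred coordinates for exact translation equivariance
    Amat <- cbind(u, v, 1)
    rhs <- -(u^2 + v^2)
    co <- stats::lm.fit(Amat, rhs)$coefficients
    cy <- -co[1] / 2; cz <- -co[2] / 2
    radius <- sqrt(cy^2 + cz^2 - co[3])
    # Gauss-Newton refinement of the geometric fit: the algebraic solution
    # is slightly biased under boundary noise, so polish (cy, cz, R) on the
    # true objective sum (|p_i - c| - R)^2
    par <- c(cy, cz, radius)
    for (it in 1:100) {
      d <- sqrt((u - par[1])^2 + (v - par[2])^2)
      d[d < 1e-12] <- 1e-12
      res <- d - par[3]
      J <- cbind(-(u - par[1]) / d, -(v - par[2]) / d, -1)
      step <- tryCatch(solve(crossprod(J), crossprod(J, -res)),
                       error = function(e) NULL)
      if (is.null(step)) break
      par <- par + as.numeric(step)
      if (max(abs(step)) < 1e-12 * max(1, par[3])) break
    }
    radius <- par[3]
    center <- c(par[1] + my, par[2] + mz)
  } else {
    if (n_triples < 1) tz_domain_error("n_triples must be >= 1")
    if (is.null(seed))
      tz_domain_error("triples_mean requires an explicit seed")
    centers <- with_seed(seed, {
      idx <- if (n >= 9) {
        b1 <- floor(n / 3); b2 <- floor(2 * n / 3)
        cbind(sample.int(b1, n_triples, replace = TRUE),
              b1 + sample.int(b2 - b1, n_triples, replace = TRUE),
              b2 + sample.int(n - b2, n_triples, replace = TRUE))
      } else matrix(sample.int(n, 3 * n_triples, replace = TRUE), ncol = 3)
      idx <- idx[idx[, 1] != idx[, 2] & idx[, 1] != idx[, 3] &
                 idx[, 2] != idx[, 3], , drop = FALSE]
      out <- matrix(NA_real_, nrow(idx), 2)
      for (i in seq_len(nrow(idx))) {
        cc <- tryCatch(
          circumcenter(c(y[idx[i, 1]], z[idx[i, 1]]),
                       c(y[idx[i, 2]], z[idx[i, 2]]),
                       c(y[idx[i, 3]], z[idx[i, 3]])),
          tz_degenerate_error = function(e) NULL)
        if (!is.null(cc)) out[i, ] <- cc
      }
      out[stats::complete.cases(out), , drop = FALSE]
    })
    if (nrow(centers) == 0)
      tz_degenerate_error("all sampled triples were degenerate (collinear points)")
    center <- colMeans(centers)
    radius <- mean(sqrt((y - center[1])^2 + (z - center[2])^2))
  }
  dist <- sqrt((y - center[1])^2 + (z - center[2])^2)
  structure(list(center_y = unname(center[1]),
                 center_z = unname(center[2]),
                 radius = unname(radius),
                 rms_residual = sqrt(mean((dist - radius)^2)),
                 n_points = n,
                 strategy = strategy),
            class = "circle_estimate")
}

#' @export
print.circle_estimate <- function(x, ...) {
  cat(sprintf(
    "Bead circle estimate (%s): center (y, z) = (%.3f, %.3f) px, radius %.3f px\n",
    x$strategy, x$center_y, x$center_z, x$radius))
  cat(sprintf("  rms residual %.4f px over %d boundary points\n",
              x$rms_residual, x$n_points))
  invisible(x)
}

#' Locate the bead in one image
#'
#' Convenience pipeline: [binarize()] then [edge_points()] then
#' [robust_center()].
#'
#' @param image A [bead_image()].
#' @param ... Passed to [robust_center()].
#' @inheritParams binarize
#' @return A `circle_estimate`.
#' @export
locate_bead <- function(image, method = "otsu", threshold = NULL, ...) {
  mask <- binarize(image, method = method, threshold = threshold)
  robust_center(edge_points(mask), ...)
}

#' Bead-centre displacement between two frames
#'
#' Componentwise difference of two centre estimates converted to metres.
#' Tracks deflection simultaneously in Y and Z; antisymmetric in its
#' arguments.
#'
#' @param current,reference `circle_estimate`s from the same optical
#'   configuration.
#' @param pixel_size Physical pixel size (m/px).
#' @return Named numeric `c(dy, dz)` in metres.
#' @export
displacement <- function(current, reference, pixel_size) {
  stopifnot(inherits(current, "circle_estimate"),
            inherits(reference, "circle_estimate"))
  assert_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  c(dy = (current$center_y - reference$center_y) * pixel_size,
    dz = (current$center_z - reference$center_z) * pixel_size)
}

#' Relative uncertainty from a centre-localization error
#'
#' Propagates a bead-centre localization error of `center_error_px` pixels
#' on a bead imaged at `diameter_px` pixels into a relative force-constant
#' uncertainty, as the ratio `center_error / diameter` expressed in
#' percent. Under this model a 1-px error on a 500-px bead gives 0.2% and
#' on a 1500-px bead about 0.07%.
#'
#' @param diameter_px Imaged bead diameter (px), > 0.
#' @param center_error_px Centre localization error (px), >= 0.
#' @return Relative uncertainty in percent.
#' @examples
#' localization_uncertainty(500, 1)   # 0.2
#' localization_uncertainty(1500, 1)  # ~0.067
#' @export
localization_uncertainty <- function(diameter_px, center_error_px) {
  assert_number(diameter_px, "diameter_px", lower = 0, strict_lower = TRUE)
  assert_number(center_error_px, "center_error_px", lower = 0)
  100 * center_error_px / diameter_px
}
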