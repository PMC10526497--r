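# Homogeneous-coordinate geometry for a 2D world whose x axis carries depth.
# Points are plain numeric 3-vectors (x, y, w); image points are 2-vectors
# (1, c) with c = 0 at the centre of the camera plane. Transforms are 3x3
# matrices acting on column vectors.

#' Construct a homogeneous 2D point
#'
#' Points live in the projective plane: `(x, y, w)` and `(c*x, c*y, c*w)` for
#' any `c != 0` denote the same Cartesian point `(x/w, y/w)`. Depth is carried
#' on the x coordinate throughout the package.
#'
#' @param x,y Cartesian coordinates (world length units).
#' @param w Projective coordinate, default 1.
#' @return Numeric vector `c(x, y, w)`.
#' @export
hom_point <- function(x, y, w = 1) c(x, y, w)

#' Normalize a homogeneous point to the w = 1 plane
#'
#' @param p Numeric 3-vector `(x, y, w)` with `w != 0`.
#' @return The equivalent point with third component exactly 1.
#' @export
normalize_hom <- function(p) {
  if (p[3] == 0) stop("degenerate homogeneous point: w = 0 (point at infinity)")
  p / p[3]
}

#' Rotation-then-translation transform
#'
#' Returns the 3x3 matrix `rotation(theta) %*% translation(lx, ly)`, i.e. the
#' point is first translated by `(lx, ly)` and then rotated by `theta`
#' (counter-clockwise, measured from the depth axis).
#'
#' @param theta Rotation angle in radians.
#' @param lx,ly Translation components (world length).
#' @return 3x3 affine transform matrix with last row `(0, 0, 1)`.
#' @export
make_rototranslation <- function(theta, lx = 0, ly = 0) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0,
           -st, ct, 0,
           ct * lx - st * ly, st * lx + ct * ly, 1), 3L, 3L)
}

#' Extrinsic transform of one eye
#'
#' Maps world coordinates into the reference frame of an eye sitting at
#' `(0, l)` and rotated by the absolute angle `theta`:
#' \deqn{T = \begin{pmatrix} c_\theta & s_\theta & -l s_\theta \\
#'                           -s_\theta & c_\theta & -l c_\theta \\
#'                           0 & 0 & 1 \end{pmatrix}}
#' The eye's optical axis is the relative x axis; a point on the axis has
#' relative y = 0 and projects to the centre of that eye's camera plane.
#'
#' @param theta Absolute eye angle (radians, from the depth axis).
#' @param l Signed distance of the eye from the origin along the y axis.
#' @return 3x3 transform matrix.
#' @export
make_eye_transform <- function(theta, l) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, -st, 0,
           st, ct, 0,
           -l * st, -l * ct, 1), 3L, 3L)
}

# Derivative of make_eye_transform with respect to theta (needed for the
# backprop of relative-point errors onto the eye-angle belief).
deye_dtheta <- function(theta, l) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(-st, -ct, 0,
           ct, -st, 0,
           -l * ct, l * st, 0), 3L, 3L)
}

#' Apply a transform to a homogeneous point
#'
#' Plain matrix-vector product `T %*% p`; no normalization is performed, so a
#' projective transform may move the point off the w = 1 plane.
#'
#' @param Tm 3x3 transform matrix.
#' @param p Numeric 3-vector.
#' @return Numeric 3-vector.
#' @export
apply_transform <- function(Tm, p) as.numeric(Tm %*% p)

#' Pinhole projection onto a camera plane
#'
#' For a normalized point `r = (x, y, 1)` in an eye's reference frame, the
#' projected image coordinate is `c = f * y / x`, carried homogeneously as
#' `(1, c)` so that the centre of the plane is `(1, 0)`.
#'
#' @param r Numeric 3-vector, normalized (w = 1), with `r[1] != 0`.
#' @param f Focal length (> 0, world length).
#' @return Numeric 2-vector `(1, c)`.
#' @export
project_to_camera <- function(r, f) {
  if (r[1] == 0) stop("degenerate projection: point at zero depth in the camera frame")
  c(1, f * r[2] / r[1])
}

#' Back-propagate an error through a transform onto the input point
#'
#' Gradient of `T %*% p` with respect to `p`, contracted with an error vector:
#' returns `t(T) %*% err`.
#'
#' @param Tm 3x3 transform matrix.
#' @param err Numeric 3-vector of prediction error.
#' @return Numeric 3-vector.
#' @export
backprop_point <- function(Tm, err) as.numeric(crossprod(Tm, err))

#' Back-propagate an error onto a scalar transform parameter
#'
#' The directional derivative of `t(err) %*% T(param) %*% p` with respect to
#' `param`: the element-wise product of `dT/dparam` with the outer product
#' `err %o% p`, summed over all entries.
#'
#' @param dT_dparam 3x3 matrix of entry-wise derivatives of the transform.
#' @param err Numeric 3-vector of prediction error.
#' @param mu_r Numeric 3-vector, the point the transform is applied to.
#' @return Scalar gradient.
#' @export
backprop_param <- function(dT_dparam, err, mu_r) {
  sum(dT_dparam * (err %o% mu_r))
}

#' Back-propagate an image-coordinate error through the projection
#'
#' Gradient of `c = f * r_y / r_x` with respect to `(r_x, r_y)`, contracted
#' with a scalar error: `(-f * r_y / r_x^2 * err, f / r_x * err)`.
#'
#' @param r Numeric 3-vector in the camera frame, `r[1] != 0`.
#' @param f Focal length.
#' @param err Scalar image-coordinate error.
#' @return Numeric 2-vector, gradient with respect to `(r_x, r_y)`.
#' @export
backprop_projection <- function(r, f, err) {
  if (r[1] == 0) stop("degenerate projection gradient: zero depth")
  c(-f * r[2] / r[1]^2 * err, f / r[1] * err)
}

#' Closed-form stereo triangulation with parallel eyes
#'
#' With both eyes parallel (`theta = 0`) at `(0, -L)` and `(0, +L)`, the image
#' coordinates satisfy `c_i = f * (y - l_i) / x`, so the disparity gives
#' `x = 2 f L / (c0 - c1)` and `y = x * c0 / f + l0`. This is the geometric
#' oracle used to validate the inference machinery.
#'
#' @param c0,c1 Image coordinates of the two eyes (eye 0 at `y = -L`).
#' @param f Focal length.
#' @param L Inter-eye half-distance.
#' @return Numeric 2-vector `(x, y)`.
#' @export
triangulate_parallel <- function(c0, c1, f, L) {
  d <- c0 - c1
  if (d == 0) stop("zero disparity: target at infinity")
  x <- 2 * f * L / d
  y <- x * c0 / f - L
  c(x, y)
}
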