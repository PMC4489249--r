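# Pure vector/plane mathematics shared by all detectors. Angles are always
# reported in degrees; coordinates in Angstrom.

#' Euclidean distance between two points
#'
#' @param a,b Numeric xyz vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
#' @examples
#' point_distance(c(0, 0, 0), c(3, 4, 0)) # 5
point_distance <- function(a, b) {
  sqrt(sum((a - b)^2))
}

#' Interior angle at a vertex
#'
#' @param a,vertex,c Numeric xyz vectors; the angle is measured at `vertex`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
#' @examples
#' point_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
point_angle <- function(a, vertex, c) {
  u <- a - vertex
  w <- c - vertex
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu < 1e-12 || nw < 1e-12) {
    stop("undefined geometry: zero-length arm at angle vertex")
  }
  cosang <- sum(u * w) / (nu * nw)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Least-squares plane through a set of points
#'
#' Fits the total-least-squares plane (via SVD of the centered coordinates).
#' The normal sign is fixed deterministically: positive z-component, ties
#' broken by positive y then positive x, so serialized geometry is
#' reproducible.
#'
#' @param points Numeric matrix (n x 3), n >= 3, not collinear.
#' @return An object of class `plane3d` with fields `centroid`, `normal`
#'   (unit vector) and `planarity_rmsd` (root-mean-square point-to-plane
#'   distance, Angstrom).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 3) {
    stop("fit_plane needs at least 3 points with xyz coordinates")
  }
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate geometry: points are collinear")
  }
  n <- sv$v[, 3]
  tol <- 1e-10
  flip <- if (abs(n[3]) > tol) {
    n[3] < 0
  } else if (abs(n[2]) > tol) {
    n[2] < 0
  } else {
    n[1] < 0
  }
  if (flip) n <- -n
  d <- as.numeric(x %*% n)
  structure(
    list(
      centroid = as.numeric(ctr),
      normal = as.numeric(n),
      planarity_rmsd = sqrt(mean(d^2))
    ),
    class = "plane3d"
  )
}

#' Acute angle between two planes
#'
#' @param p1,p2 `plane3d` objects from [fit_plane()].
#' @return Angle between the plane normals folded into \[0, 90\] degrees.
#' @export
plane_angle <- function(p1, p2) {
  cosang <- abs(sum(p1$normal * p2$normal))
  cosang <- min(1, cosang)
  acos(cosang) * 180 / pi
}

#' Lateral offset of a point relative to a plane centroid
#'
#' In-plane distance between the plane centroid and the orthogonal
#' projection of `point` onto the plane.
#'
#' @param p A `plane3d` object.
#' @param point Numeric xyz vector.
#' @return Offset in Angstrom.
#' @export
projected_offset <- function(p, point) {
  v <- point - p$centroid
  v_in <- v - sum(v * p$normal) * p$normal
  sqrt(sum(v_in^2))
}
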