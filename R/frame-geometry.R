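# Nitroxide label frames from atom coordinates: best-fit ring plane,
# oxygen projection, axis construction, d1 dihedral and syn/anti states.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

#' Least-squares plane of a set of points
#'
#' Fits the orthogonal-regression plane through `points` (n x 3 matrix) and
#' returns its centroid and unit normal. The normal sign follows the
#' right-hand rule of the first three points (cross product of the first two
#' edge vectors), so a consistent atom ordering yields a consistent normal.
#'
#' @param points numeric matrix, one point per row, >= 3 rows.
#' @return list with `centroid` (3-vector) and `normal` (unit 3-vector).
#' @keywords internal
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points to fit a plane", call. = FALSE)
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  sv <- svd(X)
  # degenerate (collinear) input: second singular value vanishes
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12)) {
    stop("ring atoms are collinear: no unique plane", call. = FALSE)
  }
  normal <- sv$v[, 3L]
  ref <- pracma::cross(points[2L, ] - points[1L, ], points[3L, ] - points[1L, ])
  if (sum(normal * ref) < 0) normal <- -normal
  list(centroid = ctr, normal = .unit(normal))
}

#' Project the nitroxide oxygen into the isoindoline ring plane
#'
#' Force fields with generic atom types can push the N-O oxygen out of the
#' aromatic ring plane; for spin-physics purposes the oxygen is virtually
#' repositioned by orthogonal projection onto the least-squares plane of the
#' ring atoms. The operation is idempotent and is the identity for an oxygen
#' already in the plane.
#'
#' @param ring_atoms matrix (>= 3 x 3) of ring heavy-atom coordinates
#'   (Angstrom).
#' @param O_coord 3-vector, oxygen coordinate (Angstrom).
#' @return 3-vector: the projected oxygen coordinate.
#' @export
project_oxygen_into_plane <- function(ring_atoms, O_coord) {
  pl <- fit_plane(ring_atoms)
  O_coord <- as.numeric(O_coord)
  d <- sum((O_coord - pl$centroid) * pl$normal)
  O_coord - d * pl$normal
}

#' Nitroxide frame constructor
#'
#' @param origin 3-vector (Angstrom), spin-center position.
#' @param x_axis,y_axis,z_axis orthonormal right-handed unit vectors.
#' @param d1_point,d1_dir anchor point and unit direction of the d1 bond
#'   axis (the rotatable amine bridge between the purine scaffold and the
#'   isoindoline ring) used for 180 degree conformer flips. Defaults: the
#'   in-plane x axis through the spin center.
#' @return object of class `nitroxide_frame`.
#' @export
nitroxide_frame <- function(origin, x_axis, y_axis, z_axis,
                            d1_point = origin, d1_dir = x_axis) {
  fr <- list(origin = as.numeric(origin),
             x = .unit(as.numeric(x_axis)),
             y = .unit(as.numeric(y_axis)),
             z = .unit(as.numeric(z_axis)),
             d1_point = as.numeric(d1_point),
             d1_dir = .unit(as.numeric(d1_dir)))
  R <- cbind(fr$x, fr$y, fr$z)
  dev <- max(abs(crossprod(R) - diag(3)))
  if (dev > 1e-5)
    stop("frame axes are not orthonormal", call. = FALSE)
  if (dev > 1e-12) {
    # snap to the nearest rotation (polar decomposition); absorbs the
    # rounding of axes printed at finite precision
    sv <- svd(R)
    R <- sv$u %*% t(sv$v)
    fr$x <- R[, 1]; fr$y <- R[, 2]; fr$z <- R[, 3]
  }
  if (sum(pracma::cross(fr$x, fr$y) * fr$z) < 0)
    stop("frame axes are not right-handed", call. = FALSE)
  class(fr) <- "nitroxide_frame"
  fr
}

#' @export
print.nitroxide_frame <- function(x, ...) {
  cat("Nitroxide frame\n")
  cat(sprintf("  origin (A): %8.3f %8.3f %8.3f\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x", "y", "z"))
    cat(sprintf("  %s axis:     %8.4f %8.4f %8.4f\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

#' Rotation matrix of a frame
#'
#' Columns are the x, y, z axes, so `frame_matrix(f) %*% v_local` maps
#' label-frame components to the laboratory frame.
#' @param frame a `nitroxide_frame`.
#' @return 3 x 3 rotation matrix.
#' @export
frame_matrix <- function(frame) cbind(frame$x, frame$y, frame$z)

#' Build a nitroxide axis frame from label atoms
#'
#' Axis convention: x points from the nitrogen to the (plane-projected)
#' oxygen; z is the normal of the least-squares isoindoline plane, with its
#' sign fixed by the ring-atom ordering (right-hand rule on the first three
#' ring atoms); y = z x x completes the right-handed set. The origin is the
#' midpoint of the N-O bond after oxygen projection, the standard point
#' approximation for the nitroxide spin density. If the nitrogen itself
#' sits slightly out of plane, x is orthogonalized against z.
#'
#' @param label list with elements `ring` (matrix of ring heavy atoms),
#'   `N`, `O` (3-vectors) and optionally `d1` (4 x 3 matrix of the atoms
#'   defining the d1 dihedral; rows 2-3 span the bond axis used for
#'   conformer flips). Coordinates in Angstrom.
#' @return a [nitroxide_frame].
#' @export
build_frame <- function(label) {
  pl <- fit_plane(label$ring)
  Oproj <- project_oxygen_into_plane(label$ring, label$O)
  NO <- Oproj - as.numeric(label$N)
  if (sqrt(sum(NO^2)) < 1e-6) stop("zero-length N-O vector", call. = FALSE)
  z <- pl$normal
  x <- NO - sum(NO * z) * z        # exact for an in-plane nitrogen
  x <- .unit(x)
  y <- pracma::cross(z, x)
  origin <- (as.numeric(label$N) + Oproj) / 2
  if (!is.null(label$d1)) {
    d1 <- as.matrix(label$d1)
    axis_dir <- .unit(d1[3L, ] - d1[2L, ])
    nitroxide_frame(origin, x, y, z, d1_point = d1[3L, ], d1_dir = axis_dir)
  } else {
    nitroxide_frame(origin, x, y, z)
  }
}

#' Signed dihedral angle
#'
#' Standard IUPAC-signed torsion p1-p2-p3-p4 in degrees, in (-180, 180].
#' A cis (eclipsed, both outer atoms on the same side) arrangement gives 0,
#' trans gives 180. Positive angles are clockwise rotations of bond 3-4
#' relative to bond 1-2 when viewed down the p2->p3 axis.
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return angle in degrees.
#' @export
dihedral_d1 <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 * sqrt(sum(b1^2) * sum(b2^2)) ||
      sqrt(sum(n2^2)) < 1e-9 * sqrt(sum(b2^2) * sum(b3^2)))
    stop("collinear atoms: dihedral undefined", call. = FALSE)
  m1 <- pracma::cross(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify a d1 dihedral as syn or anti
#'
#' The d1 free-energy landscape has minima near 0 (syn) and 180 degrees
#' (anti); substates around +-30-35 degrees belong to syn and those around
#' 140-150 degrees to anti. The classifier therefore uses |d1| < 90 for syn;
#' the boundary |d1| = 90 itself is assigned to anti (its population is
#' negligible since it sits on the rotational barrier).
#'
#' @param d1 angle in degrees, in (-180, 180].
#' @return `"syn"` or `"anti"` (vectorized).
#' @export
classify_conformer <- function(d1) {
  stopifnot(all(is.finite(d1)), all(d1 > -180 - 1e-9), all(d1 <= 180 + 1e-9))
  ifelse(abs(d1) < 90, "syn", "anti")
}

#' Spin-pair geometry
#'
#' Bundles the two nitroxide frames of one ensemble member with the derived
#' inter-spin distance and direction.
#'
#' @param frame_A,frame_B `nitroxide_frame` objects (origins in Angstrom).
#' @param conformer character of length 2: syn/anti state of each label.
#' @return object of class `spin_pair` with fields `r` (nm), `u` (unit
#'   inter-spin vector, lab frame, pointing A -> B), `frame_A`, `frame_B`,
#'   `conformer`.
#' @export
spin_pair <- function(frame_A, frame_B, conformer = c("syn", "syn")) {
  stopifnot(inherits(frame_A, "nitroxide_frame"), inherits(frame_B, "nitroxide_frame"))
  conformer <- match.arg(conformer, c("syn", "anti"), several.ok = TRUE)
  if (length(conformer) != 2L) stop("conformer must have one state per label", call. = FALSE)
  d <- frame_B$origin - frame_A$origin
  r <- sqrt(sum(d^2)) / 10  # Angstrom -> nm
  if (r <= 0) stop("coincident spin centers", call. = FALSE)
  structure(list(r = r, u = d / sqrt(sum(d^2)), frame_A = frame_A,
                 frame_B = frame_B, conformer = conformer),
            class = "spin_pair")
}

#' @export
print.spin_pair <- function(x, ...) {
  cat(sprintf("Spin pair: r = %.3f nm, conformer %s-%s\n",
              x$r, x$conformer[1], x$conformer[2]))
  ang <- function(fr) acos(min(1, abs(sum(fr$z * x$u)))) * 180 / pi
  cat(sprintf("  angle(z, u): A %.1f deg, B %.1f deg\n",
              ang(x$frame_A), ang(x$frame_B)))
  invisible(x)
}

#' Apply a rigid motion to a frame
#' @param frame a `nitroxide_frame`.
#' @param R 3 x 3 rotation matrix.
#' @param shift translation 3-vector (Angstrom).
#' @return transformed frame.
#' @export
transform_frame <- function(frame, R = diag(3), shift = c(0, 0, 0)) {
  nitroxide_frame(origin = as.numeric(R %*% frame$origin) + shift,
                  x_axis = as.numeric(R %*% frame$x),
                  y_axis = as.numeric(R %*% frame$y),
                  z_axis = as.numeric(R %*% frame$z),
                  d1_point = as.numeric(R %*% frame$d1_point) + shift,
                  d1_dir = as.numeric(R %*% frame$d1_dir))
}

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- .unit(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
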