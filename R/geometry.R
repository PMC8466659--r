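# Pure geometry kernels: centroids, ring-plane normals, folded angles,
# pairwise distances, van der Waals radii.  Coordinates are in Angstrom
# throughout; angles are in degrees.

# Numerical slack applied to every inclusive threshold comparison so that a
# geometric parameter constructed exactly at a printed cutoff (e.g. a D-A
# distance of 3.50 A) is never rejected because of floating-point round-trip
# noise in distance/angle re-measurement.  Orders of magnitude smaller than
# any physically meaningful difference.
.geom_eps <- 1e-9

.as_coord_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.numeric(points) && length(points) == 3L) {
    m <- matrix(points, ncol = 3L)
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
  } else {
    stop("cannot interpret 'points' as 3D coordinates")
  }
  if (ncol(m) != 3L) stop("coordinates must have 3 columns")
  if (!all(is.finite(m))) stop("coordinates must be finite")
  m
}

#' Centroid of a point set
#'
#' Arithmetic mean of 3D coordinates, e.g. the centroid (ctd) of an aromatic
#' ring used by the pi-stacking and pi-cation detectors.
#'
#' @param points numeric matrix with 3 columns (one row per point), a list of
#'   length-3 numeric vectors, or a single length-3 vector.
#' @return numeric length-3 vector.
#' @export
#' @examples
#' centroid(rbind(c(0, 0, 0), c(2, 0, 0)))
centroid <- function(points) {
  m <- .as_coord_matrix(points)
  if (nrow(m) == 0L) stop("centroid of an empty point set is undefined")
  colMeans(m)
}

#' Unit normal of the least-squares plane through a ring
#'
#' Fits a plane to >= 3 non-collinear points by singular value decomposition
#' of the centred coordinates and returns the unit vector along the smallest
#' singular direction.  The sign of the normal is arbitrary; consumers must
#' fold angles to \[0, 90\] degrees (see [angle_between()]).
#'
#' @inheritParams centroid
#' @return unit numeric length-3 vector orthogonal to the fitted plane.
#' @export
ring_normal <- function(points) {
  m <- .as_coord_matrix(points)
  if (nrow(m) < 3L) stop("ring_normal needs at least 3 points")
  centred <- sweep(m, 2L, colMeans(m))
  sv <- svd(centred)
  # degenerate (collinear) point sets have two near-zero singular values
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], .Machine$double.eps)) {
    stop("ring_normal: points are collinear or degenerate")
  }
  n <- sv$v[, 3L]
  n / sqrt(sum(n^2))
}

#' Angle between two vectors, in degrees
#'
#' With `fold_to_90 = TRUE` angles above 90 degrees are mapped to their
#' supplement (theta -> 180 - theta).  This folding convention resolves the
#' sign ambiguity of least-squares ring normals before testing angular
#' windows whose upper bound is at most 90 degrees.
#'
#' @param u,v nonzero numeric length-3 vectors.
#' @param fold_to_90 logical; fold the result into \[0, 90\]?
#' @return angle in degrees, in \[0, 180\] (or \[0, 90\] when folded).
#' @export
#' @examples
#' angle_between(c(1, 0, 0), c(1, 1, 0))          # 45
#' angle_between(c(1, 0, 0), c(-1, 0, 0), TRUE)   # 0
angle_between <- function(u, v, fold_to_90 = FALSE) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("angle_between: zero vector")
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  theta <- acos(ct) * 180 / pi
  if (fold_to_90 && theta > 90) theta <- 180 - theta
  theta
}

#' Minimum pairwise distance between two point sets
#'
#' Exact minimum over all cross pairs, e.g. the smallest interatomic distance
#' between two aromatic rings ("min" in the stacking criteria).
#'
#' @param a,b nonempty coordinate sets (see [centroid()] for accepted forms).
#' @return distance in Angstrom.
#' @export
min_pairwise_distance <- function(a, b) {
  ma <- .as_coord_matrix(a)
  mb <- .as_coord_matrix(b)
  if (nrow(ma) == 0L || nrow(mb) == 0L) {
    stop("min_pairwise_distance: empty point set")
  }
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, vectorized over the cross product set
  cross <- tcrossprod(ma, mb)
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * cross
  sqrt(max(0, min(d2)))
}

.dist3 <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

# ---- van der Waals radii ----------------------------------------------------

#' Load a van der Waals radius table
#'
#' The bundled table (`inst/extdata/vdw_radii.txt`) uses the Bondi (1964)
#' radii for main-group elements, supplemented with published values for
#' metals and the heavier elements Bondi did not list.  Because contact
#' criteria are sensitive to the radius set, any two-column whitespace
#' separated text file (element symbol, radius in Angstrom) can be
#' substituted.
#'
#' @param path path to a two-column text file; `NULL` for the bundled table.
#' @return named numeric vector of radii (Angstrom), class `vdw_table`.
#' @export
load_vdw_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_radii.txt", package = "resifp",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("element", "radius"),
                           stringsAsFactors = FALSE)
  if (any(!is.finite(tab$radius)) || any(tab$radius <= 0)) {
    stop("vdW radii must be positive finite numbers")
  }
  r <- stats::setNames(tab$radius, tab$element)
  class(r) <- "vdw_table"
  r
}

.vdw_lookup <- function(element, table) {
  idx <- match(element, names(table))
  if (anyNA(idx)) {
    stop("element(s) not in vdW radius table: ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  unname(unclass(table)[idx])
}

#' van der Waals interaction distance for an element pair
#'
#' Sum of the two van der Waals radii plus a tolerance factor (0.6 Angstrom
#' by default), the cutoff used by the residue-residue contact criterion.
#'
#' @param el1,el2 element symbols.
#' @param table a `vdw_table` from [load_vdw_table()].
#' @param tolerance additive tolerance in Angstrom.
#' @return distance in Angstrom.
#' @export
#' @examples
#' vdw_sum("C", "C", tolerance = 0.6)  # 1.7 + 1.7 + 0.6 = 4.0
vdw_sum <- function(el1, el2, table = load_vdw_table(), tolerance = 0.6) {
  .vdw_lookup(el1, table) + .vdw_lookup(el2, table) + tolerance
}
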