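#' 3D scalar volume with physical geometry
#'
#' The basic carrier of all voxel computation: a dense 3D array of
#' intensities (Hounsfield-value-like, dimensionless) together with the
#' physical mapping of the grid.  World coordinates follow the DICOM LPS
#' convention, in millimetres:
#' \deqn{world = origin + orientation \cdot (index \circ spacing)}
#' with zero-based indices, i.e. \code{origin} is the world position of the
#' centre of the first voxel.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel edge length per axis in mm;
#'   strictly positive.
#' @param origin numeric length-3, world position (mm) of the centre of
#'   voxel (0,0,0).
#' @param orientation 3x3 direction matrix; must be orthonormal with
#'   determinant +1.
#' @return An object of class \code{volume_image}.
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0),
                         orientation = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("`data` must be a non-empty 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values", call. = FALSE)
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6 ||
      abs(det(orientation) - 1) > 1e-6)
    stop("`orientation` must be orthonormal with determinant +1",
         call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin,
         orientation = orientation),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_image> ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n  origin (", paste(signif(x$origin, 4), collapse = ", "),
      ") mm, intensity range [",
      paste(signif(range(x$data), 5), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

is_volume_image <- function(x) inherits(x, "volume_image")

#' Voxel volume of a grid
#' @param vol a \code{volume_image}.
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Convert voxel indices to world coordinates
#'
#' Indices are zero-based (the convention of the geometry model); the first
#' voxel of the array has index (0,0,0).
#'
#' @param vol a \code{volume_image}.
#' @param idx n x 3 matrix of zero-based (possibly fractional) indices.
#' @return n x 3 matrix of world points (LPS, mm).
#' @export
index_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx %*% diag(vol$spacing) %*% t(vol$orientation), 2L, vol$origin, "+")
}

#' Convert world coordinates to (fractional, zero-based) voxel indices
#' @param vol a \code{volume_image}.
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of fractional zero-based indices.
#' @export
world_to_index <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts, 2L, vol$origin, "-") %*% vol$orientation %*% diag(1 / vol$spacing)
}

#' World coordinates of every voxel centre
#'
#' Centres are returned in array (column-major) order, matching
#' \code{as.vector(vol$data)}.
#'
#' @param vol a \code{\link{volume_image}}.
#' @return an (n1*n2*n3) x 3 matrix of world points (mm).
#' @export
voxel_centers_world <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(
    rep.int(seq_len(d[1L]) - 1, d[2L] * d[3L]),
    rep.int(rep(seq_len(d[2L]) - 1, each = d[1L]), d[3L]),
    rep(seq_len(d[3L]) - 1, each = d[1L] * d[2L])
  )
  index_to_world(vol, idx)
}

# Physical extent of the grid: voxel boxes, not centres.  Rows lo/hi, one
# column per world axis.  Only exact for axis-aligned orientations; for a
# general rotation this is the bounding box of the rotated grid.
volume_extent <- function(vol) {
  d <- dim(vol$data)
  corner_idx <- as.matrix(expand.grid(c(-0.5, d[1L] - 0.5),
                                      c(-0.5, d[2L] - 0.5),
                                      c(-0.5, d[3L] - 0.5)))
  w <- index_to_world(vol, corner_idx)
  rbind(lo = apply(w, 2L, min), hi = apply(w, 2L, max))
}

#' Sample a volume at arbitrary world points by trilinear interpolation
#'
#' Points outside the grid of voxel centres are clamped to the border value
#' (no extrapolation beyond the physical extent is ever produced).
#'
#' @param vol a \code{volume_image}.
#' @param pts n x 3 matrix of world points (mm).
#' @return numeric vector of interpolated intensities.
#' @export
sample_trilinear <- function(vol, pts) {
  d <- dim(vol$data)
  ij <- world_to_index(vol, pts)
  # clamp to the centre lattice so border values are replicated
  for (a in 1:3) ij[, a] <- pmin(pmax(ij[, a], 0), d[a] - 1)
  i0 <- pmin(floor(ij), rep(d, each = nrow(ij)) - 2)
  i0[i0 < 0] <- 0
  f <- ij - i0
  if (any(d == 1L)) { # degenerate axes: no interpolation along them
    for (a in which(d == 1L)) { i0[, a] <- 0; f[, a] <- 0 }
  }
  g <- function(dx, dy, dz) {
    vol$data[cbind(i0[, 1] + 1 + min(dx, d[1L] - 1L),
                   i0[, 2] + 1 + min(dy, d[2L] - 1L),
                   i0[, 3] + 1 + min(dz, d[3L] - 1L))]
  }
  # nested lerp form: exactly constant-preserving
  lerp <- function(a, b, t) a + t * (b - a)
  c00 <- lerp(g(0, 0, 0), g(1, 0, 0), f[, 1])
  c10 <- lerp(g(0, 1, 0), g(1, 1, 0), f[, 1])
  c01 <- lerp(g(0, 0, 1), g(1, 0, 1), f[, 1])
  c11 <- lerp(g(0, 1, 1), g(1, 1, 1), f[, 1])
  c0 <- lerp(c00, c10, f[, 2])
  c1 <- lerp(c01, c11, f[, 2])
  lerp(c0, c1, f[, 3])
}
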