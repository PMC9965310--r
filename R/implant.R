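# Implant model generation: a pointed forceps handle is added on the
# middle-ear-facing surface of the niche body, the union of body and handle
# is converted to a watertight triangle surface and written as binary STL.

#' Forceps handle specification
#'
#' A cuboid of \code{width} x \code{length} x \code{height} mm whose distal
#' \code{tip_fraction} of the length tapers to a vertical edge (an
#' arrow-like wedge marking the implant orientation).  The long axis points
#' along \code{direction} in cochlear-frame coordinates; the default +y
#' points toward the basal turn at the round window.
#'
#' @param width,length,height handle dimensions in mm.
#' @param tip_fraction fraction of the length forming the pointed end, in
#'   (0, 1); default 0.25.
#' @param direction unit vector in CCS coordinates for the long axis
#'   (default \code{c(0, 1, 0)}).
#' @return an object of class \code{handle_spec}.
#' @export
handle_spec <- function(width = 1.0, length = 1.5, height = 1.0,
                        tip_fraction = 0.25, direction = c(0, 1, 0)) {
  stopifnot(width > 0, length > 0, height > 0)
  if (tip_fraction <= 0 || tip_fraction >= 1)
    stop("`tip_fraction` must lie in (0, 1)", call. = FALSE)
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L, sum(direction^2) > 0)
  structure(list(width = width, length = length, height = height,
                 tip_fraction = tip_fraction,
                 direction = normalize(direction)),
            class = "handle_spec")
}

#' Add the forceps handle to a niche segmentation
#'
#' The handle base is centred on the middle-ear-facing surface of the body:
#' among kept voxels close (laterally, in the frame's y-z plane) to the
#' fill centre, the one farthest along the frame's +x axis.  The base plane
#' passes through that voxel centre, embedding the handle one voxel into
#' the body so the two stay 26-connected.  Handle voxels overlapping bone
#' are removed, as are any handle voxels disconnected from the body by that
#' clipping.
#'
#' @param seg a \code{\link{fill_niche}} result (non-empty).
#' @param bone logical bone mask on the working grid.
#' @param frame a \code{\link{fit_ccs}} frame.
#' @param spec a \code{\link{handle_spec}}.
#' @return an object of class \code{implant_model} with fields
#'   \code{body} (the segmentation), \code{handle_mask}, grid geometry and
#'   \code{mesh} (NULL until \code{\link{mask_to_mesh}} is applied).
#' @export
add_handle <- function(seg, bone, frame, spec = handle_spec()) {
  stopifnot(inherits(seg, "niche_segmentation"),
            inherits(frame, "ccs_frame"), inherits(spec, "handle_spec"))
  if (!any(seg$mask)) stop("body mask is empty", call. = FALSE)
  vol <- segmentation_volume(seg)
  d <- dim(seg$mask)
  ctrs <- voxel_centers_world(vol)
  kept <- as.vector(seg$mask)
  H <- frame$x_axis                       # height axis: toward middle ear
  L <- drop(cbind(frame$x_axis, frame$y_axis, frame$z_axis) %*%
              spec$direction)             # long axis, world coords
  L <- normalize(L - sum(L * H) * H)      # keep the base plane well defined
  W <- cross3(H, L)
  fc <- seg$params$fill_center
  lat2 <- (rowSums(sweep(ctrs, 2L, fc, "-") %*% cbind(frame$y_axis))^2 +
           rowSums(sweep(ctrs, 2L, fc, "-") %*% cbind(frame$z_axis))^2)
  near <- kept & lat2 <= max(0.5^2, min(lat2[kept]) + 1e-12)
  xk <- drop(ctrs %*% H)
  base_i <- which(near)[which.max(xk[near])]
  base <- ctrs[base_i, ]
  rel <- sweep(ctrs, 2L, base, "-")
  s <- drop(rel %*% L); t <- drop(rel %*% W); q <- drop(rel %*% H)
  hw <- spec$width / 2
  tip_len <- spec$tip_fraction * spec$length
  # half-width tapers linearly to zero over the distal tip_fraction
  taper <- pmin(1, pmax(0, (spec$length / 2 - s) / tip_len))
  # half-open intervals along every axis: unbiased voxel counts on
  # lattice-aligned bases
  inside <- s >= -spec$length / 2 & s < spec$length / 2 &
    q >= 0 & q < spec$height & t >= -hw * taper & t < hw * taper
  # handle voxels are exclusive of the body so that removing the handle
  # recovers the body mask exactly; the embedding (base plane through a
  # body surface voxel centre) still guarantees 26-connectivity
  handle <- array(inside, dim = d) & !seg$mask & !bone
  if (any(handle)) {
    # keep only handle voxels 26-connected to the body through handle+body
    un <- handle | seg$mask
    comp <- array(.flood_fill_cpp(as.vector(un), d,
                                  which(as.vector(seg$mask))[1L] - 1L, 26L),
                  dim = d)
    handle <- handle & comp
  }
  if (!any(handle))
    stop("handle entirely clipped by bone; reduce the handle dimensions ",
         "or move the base", call. = FALSE)
  structure(list(body = seg, handle_mask = handle, mesh = NULL,
                 spacing = seg$spacing, origin = seg$origin,
                 orientation = seg$orientation, handle_spec = spec,
                 base_point = base),
            class = "implant_model")
}

#' @export
print.implant_model <- function(x, ...) {
  cat("<implant_model> body ", sum(x$body$mask), " + handle ",
      sum(x$handle_mask & !x$body$mask), " voxels",
      if (!is.null(x$mesh)) paste0(", mesh ", nrow(x$mesh$faces),
                                   " triangles"), "\n", sep = "")
  invisible(x)
}

#' Convert a binary voxel mask to a watertight triangle surface
#'
#' The 0/1 mask is meshed at iso-level 0.5 between voxel centres with a
#' binary surface-net extractor (solid boxes mesh to their exact voxel
#' bounding box; vertex splitting keeps diagonal contacts 2-manifold),
#' followed by optional shrink-free Taubin smoothing (lambda = 0.5,
#' mu = -0.53).  The output is closed, 2-manifold and consistently
#' outward-oriented.
#'
#' @param mask logical 3D array (e.g. body | handle).
#' @param vol a \code{\link{volume_image}} (or anything with
#'   \code{spacing}/\code{origin}/\code{orientation}) carrying the grid
#'   geometry.
#' @param smoothing_iterations Taubin iterations (default 10; 0 disables).
#' @return an object of class \code{rwn_mesh}: list with \code{vertices}
#'   (n x 3, mm) and \code{faces} (m x 3, 1-based, outward orientation).
#' @export
mask_to_mesh <- function(mask, vol, smoothing_iterations = 10L) {
  if (!any(mask)) stop("cannot mesh an empty mask", call. = FALSE)
  stopifnot(smoothing_iterations >= 0)
  d <- dim(mask)
  nets <- .surface_nets_cpp(as.vector(mask), d)
  V <- nets$vertices   # fractional zero-based voxel indices
  Fc <- nets$faces
  geom <- volume_image(array(0, dim = c(1L, 1L, 1L)), vol$spacing,
                       vol$origin, vol$orientation)
  Vw <- index_to_world(geom, V)
  if (smoothing_iterations > 0)
    Vw <- taubin_smooth(Vw, Fc, iterations = smoothing_iterations)
  structure(list(vertices = Vw, faces = Fc), class = "rwn_mesh")
}

#' @export
print.rwn_mesh <- function(x, ...) {
  cat("<rwn_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " triangles, volume ", signif(mesh_volume(x), 5), " mm^3\n", sep = "")
  invisible(x)
}

# Taubin lambda/mu smoothing on the vertex positions; topology untouched.
taubin_smooth <- function(V, F, iterations = 10L, lambda = 0.5,
                          mu = -0.53) {
  edges <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  edges <- unique(rbind(edges, edges[, 2:1]))
  deg <- tabulate(edges[, 1L], nbins = nrow(V))
  step <- function(V, f) {
    nb <- rowsum(V[edges[, 2L], , drop = FALSE], edges[, 1L],
                 reorder = TRUE)
    avg <- nb / deg
    V + f * (avg - V)
  }
  for (i in seq_len(iterations)) {
    V <- step(V, lambda)
    V <- step(V, mu)
  }
  V
}

#' Build the surface mesh of an implant model
#'
#' @param implant an \code{\link{add_handle}} result.
#' @param smoothing_iterations forwarded to \code{\link{mask_to_mesh}}.
#' @return the \code{implant_model} with its \code{mesh} field set.
#' @export
build_implant_mesh <- function(implant, smoothing_iterations = 10L) {
  stopifnot(inherits(implant, "implant_model"))
  implant$mesh <- mask_to_mesh(implant$body$mask | implant$handle_mask,
                               implant, smoothing_iterations)
  implant
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' consistently outward-oriented surfaces.
#'
#' @param mesh an \code{rwn_mesh}.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1L], , drop = FALSE]
  b <- V[F[, 2L], , drop = FALSE]
  c <- V[F[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) +
      a[, 2L] * (b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

#' Check that a mesh is closed, 2-manifold and consistently oriented
#'
#' Every undirected edge must be shared by exactly two faces and every
#' directed half-edge used exactly once (consistent orientation).
#'
#' @param mesh an \code{rwn_mesh}.
#' @return logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  F <- mesh$faces
  he <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  key <- paste(he[, 1L], he[, 2L])
  if (anyDuplicated(key) > 0) return(FALSE)   # orientation conflict
  rkey <- paste(he[, 2L], he[, 1L])
  all(rkey %in% key)                          # every half-edge has a twin
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh an \code{rwn_mesh}.
#' @return integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  nrow(mesh$vertices) - nrow(e) + nrow(F)
}

#' Write a mesh as binary STL
#'
#' Little-endian binary STL: 80-byte header, uint32 triangle count, then 50
#' bytes per facet (normal, three vertices as float32, attribute 0).  File
#' size is exactly 84 + 50 n bytes for n triangles.
#'
#' @param mesh an \code{rwn_mesh}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "rwn_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write STL to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "rwniche binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(nrow(F), con, size = 4L, endian = "little")
  a <- V[F[, 1L], , drop = FALSE]
  b <- V[F[, 2L], , drop = FALSE]
  c <- V[F[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nl <- sqrt(rowSums(n^2)); nl[nl == 0] <- 1
  n <- n / nl
  # interleave: 12 floats per facet then a zero uint16
  dat <- t(cbind(n, a, b, c))
  for (f in seq_len(nrow(F))) {
    writeBin(as.double(dat[, f]), con, size = 4L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices are welded by exact float32 coordinate equality, so a
#' \code{\link{write_stl}} round trip reproduces the mesh up to float32
#' quantisation.
#'
#' @param path input STL path.
#' @return an \code{rwn_mesh}.
#' @export
read_stl <- function(path) {
  sz <- file.size(path)
  if (is.na(sz)) stop("STL file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", size = 4L, endian = "little")
  if (sz != 84 + 50 * nf)
    stop("malformed binary STL (size mismatch)", call. = FALSE)
  tri <- matrix(0, nrow = 3L * nf, ncol = 3L)
  for (f in seq_len(nf)) {
    vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "integer", n = 1L, size = 2L, endian = "little")
    tri[(3L * f - 2L):(3L * f), ] <- matrix(vals[4:12], ncol = 3L,
                                            byrow = TRUE)
  }
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L])
  uid <- match(key, unique(key))
  V <- tri[!duplicated(key), , drop = FALSE]
  F <- matrix(uid, ncol = 3L, byrow = TRUE)
  structure(list(vertices = V, faces = F), class = "rwn_mesh")
}
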