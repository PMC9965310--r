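# Working-region extraction: crop a cubic ROI around the estimated round
# window niche position and bring it to the internal working resolution.

#' Cubic region of interest
#'
#' @param center world point (mm) at the estimated round window niche
#'   position.
#' @param edge_length cube edge in mm (default 5, the working region used
#'   around the niche).
#' @return an object of class \code{region_of_interest}.
#' @export
region_of_interest <- function(center, edge_length = 5) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)))
  if (!is.finite(edge_length) || edge_length <= 0)
    stop("`edge_length` must be a positive number", call. = FALSE)
  structure(list(center = center, edge_length = edge_length),
            class = "region_of_interest")
}

#' Crop a cubic ROI from a volume
#'
#' Retains exactly the voxels whose centres lie in the closed cube
#' \code{[center - e/2, center + e/2]} per world axis, clamped to the parent
#' grid.  World coordinates of retained voxels are unchanged.
#'
#' @param vol a \code{\link{volume_image}}.
#' @param roi a \code{\link{region_of_interest}}.
#' @return the cropped \code{volume_image}.
#' @export
crop_roi <- function(vol, roi) {
  stopifnot(is_volume_image(vol), inherits(roi, "region_of_interest"))
  ext <- volume_extent(vol)
  if (any(roi$center < ext["lo", ] - 1e-9) ||
      any(roi$center > ext["hi", ] + 1e-9))
    stop("ROI center lies outside the volume extent", call. = FALSE)
  half <- roi$edge_length / 2
  lo_w <- roi$center - half
  hi_w <- roi$center + half
  if (any(lo_w < ext["lo", ] - 1e-9) || any(hi_w > ext["hi", ] + 1e-9))
    warning("ROI exceeds the volume extent; crop clamped to the volume")
  # index-space bounds of the world-axis-aligned cube
  d <- dim(vol$data)
  corners <- as.matrix(expand.grid(c(lo_w[1L], hi_w[1L]),
                                   c(lo_w[2L], hi_w[2L]),
                                   c(lo_w[3L], hi_w[3L])))
  ci <- world_to_index(vol, corners)
  lo_i <- pmax(ceiling(apply(ci, 2L, min) - 1e-9), 0)
  hi_i <- pmin(floor(apply(ci, 2L, max) + 1e-9), d - 1)
  if (any(lo_i > hi_i))
    stop("ROI contains no voxel centers", call. = FALSE)
  idx <- lapply(1:3, function(a) (lo_i[a]:hi_i[a]) + 1L)
  volume_image(vol$data[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE],
               vol$spacing,
               index_to_world(vol, matrix(lo_i, nrow = 1L))[1L, ],
               vol$orientation)
}

#' Resample a volume to an isotropic working resolution
#'
#' If every input spacing is already at or below \code{target} the input is
#' returned unchanged (the working resolution only ever upsamples, never
#' degrades).  Otherwise the volume is trilinearly interpolated onto an
#' isotropic grid of spacing \code{target} covering the same physical
#' extent.  Border samples are clamped, so values are never extrapolated
#' beyond the input extent.
#'
#' @param vol a \code{\link{volume_image}}.
#' @param target isotropic target spacing in mm (default 0.1, the internal
#'   working resolution).
#' @return a \code{volume_image}.
#' @export
resample_isotropic <- function(vol, target = 0.1) {
  stopifnot(is_volume_image(vol))
  if (!is.finite(target) || target <= 0)
    stop("`target` must be a positive finite number", call. = FALSE)
  if (all(vol$spacing <= target + 1e-12)) return(vol)
  d <- dim(vol$data)
  extent <- d * vol$spacing
  n_new <- pmax(1L, as.integer(round(extent / target)))
  # new grid shares the lower physical corner of the old grid
  new_origin <- vol$origin +
    as.vector(vol$orientation %*% (-vol$spacing / 2 + target / 2))
  out <- volume_image(array(0, dim = n_new), rep(target, 3L), new_origin,
                      vol$orientation)
  ctrs <- voxel_centers_world(out)
  out$data <- array(sample_trilinear(vol, ctrs), dim = n_new)
  out
}
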