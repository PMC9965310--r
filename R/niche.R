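# Niche filling: the round window niche is a half-open cavity.  Candidate
# voxels are the non-bone voxels on the middle-ear side of the membrane
# within a "water level" distance of a fill centre; the niche is the
# connected component of candidates anchored at the membrane ("crater lake"
# with the membrane as the lake bottom).

#' Fill parameters for the niche segmentation
#'
#' @param fill_center world point (mm), the centre from which the water
#'   level is measured.
#' @param level inclusion radius in mm (Euclidean distance in world
#'   coordinates), or \code{"auto"} to use the spill level.
#' @param connectivity neighbourhood for the connected component: 6, 18 or
#'   26 (default).
#' @return an object of class \code{fill_parameters}.
#' @export
fill_parameters <- function(fill_center, level = "auto", connectivity = 26L) {
  fill_center <- as.numeric(fill_center)
  stopifnot(length(fill_center) == 3L, all(is.finite(fill_center)))
  if (!identical(level, "auto")) {
    level <- as.numeric(level)
    if (!is.finite(level) || level <= 0)
      stop("`level` must be positive or \"auto\"", call. = FALSE)
  }
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  structure(list(fill_center = fill_center, level = level,
                 connectivity = connectivity),
            class = "fill_parameters")
}

# provenance codes for the label map
PROV_KEPT <- 0L
PROV_COCHLEA <- 1L
PROV_BONE <- 2L
PROV_ABOVE_LEVEL <- 3L
PROV_DISCONNECTED <- 4L

# Shared per-voxel context: side labels, distances, seed.  `side` may be
# passed in to avoid re-projecting every voxel when filling repeatedly.
fill_context <- function(vol, bone, patch, frame, center, side = NULL) {
  d <- dim(vol$data)
  stopifnot(all(dim(bone) == d))
  ctrs <- voxel_centers_world(vol)
  if (is.null(side)) side <- classify_side(patch, frame, ctrs)
  stopifnot(length(side) == prod(d))
  dist <- sqrt((ctrs[, 1L] - center[1L])^2 + (ctrs[, 2L] - center[2L])^2 +
               (ctrs[, 3L] - center[3L])^2)
  pc <- eval_surface(patch, 0.5, 0.5)[1L, ]
  dpatch <- sqrt((ctrs[, 1L] - pc[1L])^2 + (ctrs[, 2L] - pc[2L])^2 +
                 (ctrs[, 3L] - pc[3L])^2)
  list(dims = d, side = side, dist = dist, dpatch = dpatch,
       bone = as.vector(bone))
}

# Core fill on a precomputed context.  Returns list(kept, provenance) as
# vectors, or NULL if there is no candidate voxel.
fill_from_context <- function(ctx, level, connectivity) {
  middle <- ctx$side == "middle_ear"
  cand <- !ctx$bone & middle & ctx$dist <= level
  prov <- integer(length(cand))
  prov[!middle] <- PROV_COCHLEA
  prov[middle & ctx$bone] <- PROV_BONE
  prov[middle & !ctx$bone & ctx$dist > level] <- PROV_ABOVE_LEVEL
  if (!any(cand)) return(list(kept = NULL, provenance = prov, cand = cand))
  seed <- which(cand)[which.min(ctx$dpatch[cand])]
  kept <- .flood_fill_cpp(cand, ctx$dims, seed - 1L, connectivity)
  prov[cand & !kept] <- PROV_DISCONNECTED
  list(kept = kept, provenance = prov, cand = cand)
}

#' Fill the round window niche
#'
#' Candidate voxels are those that are (i) not bone, (ii) on the middle-ear
#' side of the membrane and (iii) within \code{params$level} mm (Euclidean,
#' world coordinates) of the fill centre.  The result is the connected
#' component of the candidates containing the seed voxel nearest the centre
#' of the membrane patch.  A provenance label is recorded for every voxel:
#' kept / inside_cochlea / bone / above_level / disconnected (the first
#' applicable rule, in that order).
#'
#' @param vol the working-region \code{\link{volume_image}}.
#' @param bone logical bone mask on the same grid.
#' @param patch a \code{\link{rwm_patch}}.
#' @param frame a \code{\link{fit_ccs}} frame.
#' @param params a \code{\link{fill_parameters}} with a numeric level.
#' @param side optional precomputed per-voxel side labels from
#'   \code{\link{classify_side}} (saves re-projection).
#' @return an object of class \code{niche_segmentation}: logical
#'   \code{mask}, integer \code{provenance} array (codes 0 kept, 1
#'   inside_cochlea, 2 bone, 3 above_level, 4 disconnected), and the grid
#'   geometry.
#' @export
fill_niche <- function(vol, bone, patch, frame, params, side = NULL) {
  stopifnot(is_volume_image(vol), inherits(params, "fill_parameters"))
  if (identical(params$level, "auto"))
    stop("fill_niche needs a numeric level; use estimate_spill_level first",
         call. = FALSE)
  ctx <- fill_context(vol, bone, patch, frame, params$fill_center, side)
  res <- fill_from_context(ctx, params$level, params$connectivity)
  if (is.null(res$kept)) {
    tab <- table(factor(res$provenance, levels = 0:4,
                        labels = c("kept", "inside_cochlea", "bone",
                                   "above_level", "disconnected")))
    stop("empty niche segmentation: no candidate voxel next to the ",
         "membrane (exclusions: ",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  mask <- array(res$kept, dim = ctx$dims)
  seg <- structure(
    list(mask = mask,
         provenance = array(res$provenance, dim = ctx$dims),
         spacing = vol$spacing, origin = vol$origin,
         orientation = vol$orientation, params = params),
    class = "niche_segmentation")
  stopifnot(!any(mask & bone), !any(mask & array(ctx$side == "cochlea",
                                                 dim = ctx$dims)))
  seg
}

#' @export
print.niche_segmentation <- function(x, ...) {
  cat("<niche_segmentation> ", sum(x$mask), " voxels kept (",
      signif(sum(x$mask) * prod(x$spacing), 4), " mm^3), level ",
      signif(x$params$level, 4), " mm\n", sep = "")
  invisible(x)
}

#' Estimate the spill ("water") level of the niche
#'
#' Binary search (to a quarter of a voxel edge) for the largest level at
#' which the fill does not touch any face of the working region: the level
#' at which the crater lake would spill over the lowest part of its bony
#' border and escape toward the region boundary.  If even the full region
#' diagonal does not make the fill touch a face (a cavity fully enclosed in
#' bone within the region) the diagonal is returned.
#'
#' @inheritParams fill_niche
#' @param center world fill centre (mm).
#' @param connectivity connectivity used for the trial fills (default 26).
#' @return the spill level in mm.
#' @export
estimate_spill_level <- function(vol, bone, patch, frame, center,
                                 connectivity = 26L, side = NULL) {
  stopifnot(is_volume_image(vol))
  ctx <- fill_context(vol, bone, patch, frame, as.numeric(center), side)
  d <- ctx$dims
  on_face <- array(FALSE, dim = d)
  on_face[c(1L, d[1L]), , ] <- TRUE
  on_face[, c(1L, d[2L]), ] <- TRUE
  on_face[, , c(1L, d[3L])] <- TRUE
  on_face <- as.vector(on_face)
  touches <- function(level) {
    res <- fill_from_context(ctx, level, connectivity)
    if (is.null(res$kept)) return(NA)
    any(res$kept & on_face)
  }
  lmax <- sqrt(sum((d * vol$spacing)^2))
  lmin <- min(vol$spacing)
  t0 <- touches(lmin)
  if (isTRUE(t0))
    stop("even a minimal fill reaches the region boundary: ",
         "the niche is not contained in the working region", call. = FALSE)
  if (!isTRUE(touches(lmax))) return(lmax)
  lo <- lmin; hi <- lmax
  tol <- 0.25 * min(vol$spacing)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (isTRUE(touches(mid))) hi <- mid else lo <- mid
  }
  lo
}

#' Apply the three niche exclusion rules to an arbitrary segmentation
#'
#' The semi-automated definition of the niche acts through three voxel
#' rules: (1) remove voxels inside the cochlea (behind the membrane),
#' (2) remove voxels classified as bone, (3) remove voxels above the
#' filling ("spill-over") level.  This applies each rule alone and all
#' three combined to any input mask, reporting the surviving masks and
#' removal counts — the instrument used to attribute differences between
#' manual and semi-automated segmentations to individual rules.
#'
#' @param mask logical array on the working grid.
#' @param bone logical bone mask.
#' @param patch a \code{\link{rwm_patch}}.
#' @param frame a \code{\link{fit_ccs}} frame.
#' @param level_params a \code{\link{fill_parameters}} with numeric level.
#' @param vol the working-region \code{\link{volume_image}} (for geometry).
#' @param side optional precomputed side labels.
#' @return list with logical arrays \code{step1}, \code{step2},
#'   \code{step3}, \code{all} and an integer vector \code{removed} of
#'   per-rule removal counts.
#' @export
apply_niche_rules <- function(mask, bone, patch, frame, level_params, vol,
                              side = NULL) {
  stopifnot(is_volume_image(vol), all(dim(mask) == dim(vol$data)),
            inherits(level_params, "fill_parameters"),
            !identical(level_params$level, "auto"))
  ctx <- fill_context(vol, bone, patch, frame, level_params$fill_center,
                      side)
  d <- ctx$dims
  keep1 <- array(ctx$side == "middle_ear", dim = d)
  keep2 <- !bone
  keep3 <- array(ctx$dist <= level_params$level, dim = d)
  res <- list(step1 = mask & keep1,
              step2 = mask & keep2,
              step3 = mask & keep3,
              all = mask & keep1 & keep2 & keep3)
  res$removed <- c(step1 = sum(mask) - sum(res$step1),
                   step2 = sum(mask) - sum(res$step2),
                   step3 = sum(mask) - sum(res$step3),
                   all = sum(mask) - sum(res$all))
  res
}

#' Write a provenance label map as NRRD
#'
#' Codes: 0 kept, 1 inside cochlea, 2 bone, 3 above level, 4 disconnected.
#'
#' @param seg a \code{\link{fill_niche}} result.
#' @param path output \code{.nrrd} path.
#' @return \code{path}, invisibly.
#' @export
write_provenance_nrrd <- function(seg, path) {
  stopifnot(inherits(seg, "niche_segmentation"))
  vol <- volume_image(seg$provenance + 0, seg$spacing, seg$origin,
                      seg$orientation)
  write_nrrd(vol, path, type = "short")
}

#' Extract the mask of a segmentation as a volume_image of 0/1 values
#' @param seg a \code{niche_segmentation}.
#' @return a \code{\link{volume_image}}.
#' @export
segmentation_volume <- function(seg) {
  stopifnot(inherits(seg, "niche_segmentation"))
  volume_image(seg$mask + 0, seg$spacing, seg$origin, seg$orientation)
}
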