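# End-to-end semi-automated workflow: crop -> resample -> membrane
# placement -> smoothing -> histogram threshold -> niche fill -> handle ->
# mesh -> STL, driven by a single configuration and fully deterministic
# given its seeds.

#' Pipeline configuration
#'
#' @param volume a \code{\link{volume_image}} or a path readable by
#'   \code{\link{read_volume}}.
#' @param fiducials a \code{\link{cochlear_fiducials}} or a path readable
#'   by \code{\link{read_fiducials}}.
#' @param membrane optional \code{\link{rwm_patch}} (or markups path) with
#'   user-fitted control points; when NULL the mean membrane model is
#'   placed in the cochlear frame.
#' @param membrane_offsets 4 x 3 CCS offsets for the mean model (default
#'   \code{\link{default_membrane_offsets}()}).
#' @param roi_center world point for the working-region centre; default
#'   NULL uses the round-window fiducial.
#' @param roi_edge working-region edge in mm (default 5).
#' @param resample_target internal working resolution in mm (default 0.1;
#'   volumes already at or below it are left untouched).
#' @param smoothing_voxels Gaussian pre-smoothing sigma in voxels
#'   (default 0: smoothing is an optional user step for noisy scans; a
#'   width in the order of one voxel is typical when used).
#' @param bone_threshold \code{"auto"} (histogram estimate) or a number.
#' @param fill_center \code{"auto"} (centroid of candidate voxels within
#'   1 mm of the membrane patch centre) or a world point.
#' @param fill_level \code{"auto"} (the spill level) or a level in mm.
#' @param connectivity fill connectivity (default 26).
#' @param handle a \code{\link{handle_spec}}, or NULL to skip the handle.
#' @param histogram_seed seed for the histogram fit (default 0).
#' @param side working orientation, \code{"right"} or \code{"left"}.
#' @param oval_semi_axes membrane oval semi-axes (default c(0.5, 0.5)).
#' @param mesh_smoothing Taubin iterations for the surface (default 10).
#' @param out_dir optional output directory for implant.stl,
#'   segmentation.nrrd, provenance.nrrd and report.json.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(volume, fiducials, membrane = NULL,
                            membrane_offsets = default_membrane_offsets(),
                            roi_center = NULL, roi_edge = 5,
                            resample_target = 0.1, smoothing_voxels = 0,
                            bone_threshold = "auto", fill_center = "auto",
                            fill_level = "auto", connectivity = 26L,
                            handle = handle_spec(), histogram_seed = 0L,
                            side = "right", oval_semi_axes = c(0.5, 0.5),
                            mesh_smoothing = 10L, out_dir = NULL) {
  if (is.character(volume) && !file.exists(volume))
    stop("volume path does not exist: ", volume, call. = FALSE)
  if (is.character(fiducials) && !file.exists(fiducials))
    stop("fiducials path does not exist: ", fiducials, call. = FALSE)
  stopifnot(roi_edge > 0, resample_target > 0, smoothing_voxels >= 0)
  structure(list(volume = volume, fiducials = fiducials,
                 membrane = membrane, membrane_offsets = membrane_offsets,
                 roi_center = roi_center, roi_edge = roi_edge,
                 resample_target = resample_target,
                 smoothing_voxels = smoothing_voxels,
                 bone_threshold = bone_threshold,
                 fill_center = fill_center, fill_level = fill_level,
                 connectivity = as.integer(connectivity), handle = handle,
                 histogram_seed = as.integer(histogram_seed), side = side,
                 oval_semi_axes = oval_semi_axes,
                 mesh_smoothing = as.integer(mesh_smoothing),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the semi-automated niche segmentation pipeline
#'
#' Executes, in order: ROI crop, isotropic resampling, membrane placement,
#' Gaussian pre-smoothing, histogram peak fit and bone threshold
#' estimation, bone masking, spill-level estimation, niche fill, handle
#' placement, surface extraction and (optionally) STL/report output.  The
#' run report records one entry per stage with every parameter, fitted
#' value and voxel count; reruns with an identical configuration are
#' bit-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with the working-region volume (\code{roi}), \code{frame},
#'   \code{patch}, \code{threshold}, \code{bone}, \code{segmentation},
#'   \code{implant} (with mesh), \code{level}, \code{fill_center} and the
#'   \code{report} list.
#' @export
run_semiauto_segmentation <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  stage <- function(name, ...) {
    report[[name]] <<- list(...)
  }
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }

  vol <- wrap("read_volume",
              if (is_volume_image(config$volume)) config$volume
              else read_volume(config$volume))
  fids <- wrap("fiducials",
               if (inherits(config$fiducials, "cochlear_fiducials"))
                 config$fiducials
               else read_fiducials(config$fiducials))
  frame <- wrap("fit_ccs", fit_ccs(fids, side = config$side))
  stage("fit_ccs", origin = frame$origin, side = config$side)

  center <- if (is.null(config$roi_center)) fids$rw_center
            else as.numeric(config$roi_center)
  roi <- wrap("crop_roi",
              crop_roi(vol, region_of_interest(center, config$roi_edge)))
  stage("crop_roi", center = center, edge = config$roi_edge,
        dims = dim(roi$data))

  roi <- wrap("resample_isotropic",
              resample_isotropic(roi, config$resample_target))
  stage("resample_isotropic", target = config$resample_target,
        spacing = roi$spacing, dims = dim(roi$data))

  patch <- wrap("membrane", {
    if (inherits(config$membrane, "rwm_patch")) config$membrane
    else if (is.character(config$membrane))
      read_membrane_points(config$membrane, config$oval_semi_axes)
    else place_mean_patch(frame,
                          mean_membrane_model(config$membrane_offsets),
                          config$oval_semi_axes)
  })
  stage("membrane", control_points = rbind(patch$p00, patch$p10,
                                           patch$p01, patch$p11),
        oval_semi_axes = patch$oval_semi_axes)

  sm <- wrap("smooth_intensities",
             smooth_intensities(roi, config$smoothing_voxels))
  stage("smooth_intensities", kernel_width_voxels = config$smoothing_voxels)

  if (identical(config$bone_threshold, "auto")) {
    model <- wrap("fit_histogram_peaks",
                  fit_histogram_peaks(sm, seed = config$histogram_seed))
    thr <- estimate_bone_threshold(model)
    stage("fit_histogram_peaks", centers = model$centers,
          widths = model$widths, weights = model$weights,
          seed = config$histogram_seed)
  } else {
    model <- NULL
    thr <- bone_threshold(config$bone_threshold, "user")
  }
  stage("bone_threshold", value = thr$value, source = thr$source)

  bone <- wrap("bone_mask", bone_mask(sm, thr))
  stage("bone_mask", voxels = sum(bone))

  side_labels <- wrap("classify_side",
                      classify_side(patch, frame,
                                    voxel_centers_world(roi)))

  fc <- config$fill_center
  if (identical(fc, "auto")) {
    ctrs <- voxel_centers_world(roi)
    pc <- eval_surface(patch, 0.5, 0.5)[1L, ]
    cand <- !as.vector(bone) & side_labels == "middle_ear" &
      sqrt((ctrs[, 1L] - pc[1L])^2 + (ctrs[, 2L] - pc[2L])^2 +
           (ctrs[, 3L] - pc[3L])^2) <= 1
    if (!any(cand))
      stop("pipeline stage [fill_center]: no non-bone middle-ear voxel ",
           "within 1 mm of the membrane centre", call. = FALSE)
    fc <- colMeans(ctrs[cand, , drop = FALSE])
  } else fc <- as.numeric(fc)
  stage("fill_center", center = fc,
        mode = if (identical(config$fill_center, "auto")) "auto" else
          "user")

  lvl <- config$fill_level
  if (identical(lvl, "auto")) {
    lvl <- wrap("estimate_spill_level",
                estimate_spill_level(roi, bone, patch, frame, fc,
                                     config$connectivity, side_labels))
  }
  stage("fill_level", level = lvl,
        mode = if (identical(config$fill_level, "auto")) "auto" else
          "user")

  params <- fill_parameters(fc, lvl, config$connectivity)
  seg <- wrap("fill_niche",
              fill_niche(roi, bone, patch, frame, params, side_labels))
  stage("fill_niche", kept = sum(seg$mask),
        volume_mm3 = niche_volume(seg))

  implant <- NULL
  if (!is.null(config$handle)) {
    implant <- wrap("add_handle",
                    add_handle(seg, bone, frame, config$handle))
    stage("add_handle", handle_voxels = sum(implant$handle_mask),
          dims = c(config$handle$width, config$handle$length,
                   config$handle$height))
    implant <- wrap("mask_to_mesh",
                    build_implant_mesh(implant, config$mesh_smoothing))
    stage("mask_to_mesh", vertices = nrow(implant$mesh$vertices),
          triangles = nrow(implant$mesh$faces),
          smoothing_iterations = config$mesh_smoothing)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nrrd(segmentation_volume(seg),
               file.path(config$out_dir, "segmentation.nrrd"),
               type = "short")
    write_provenance_nrrd(seg, file.path(config$out_dir,
                                         "provenance.nrrd"))
    if (!is.null(implant))
      write_stl(implant$mesh, file.path(config$out_dir, "implant.stl"))
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    stage("outputs", dir = config$out_dir)
  }

  list(roi = roi, frame = frame, patch = patch, threshold = thr,
       histogram_model = model, bone = bone, side = side_labels,
       segmentation = seg, implant = implant,
       level = lvl, fill_center = fc, report = report)
}
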