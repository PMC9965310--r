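# Synthetic temporal-bone phantom: a 5 mm working region with known ground
# truth, emulating the tri-modal CBCT intensity statistics around the round
# window niche (radio-dense bone, air-filled cavities, fluid-filled
# cochlear duct) so the full pipeline can be validated without clinical
# data.
#
# Geometry (world mm, identity orientation, region centred at the origin;
# the cochlear frame coincides with the world axes): the membrane plane is
# x = 0 with the niche cavity carved toward +x (the middle-ear direction),
# a fluid duct (scala tympani surrogate) runs behind the membrane toward
# -x, a soft-tissue slab occupies the far -y side, a middle-ear air slab
# occupies the far +z side (separated from the niche by bone, as the
# middle-ear spaces border but do not open into the modelled cube), and
# everything else is bone.  The `mouth` parameter models how the niche
# connects to the middle-ear spaces outside the region: "drain" (default)
# carves a narrow air channel from the cavity to the +x face, "sealed"
# encloses the cavity completely, "flush" (box_pit) extends the cavity
# walls to the +x face.

#' Phantom specification
#'
#' @param spacing isotropic voxel size in mm (default 0.08, the clinical
#'   reconstruction voxel size the tool targets).
#' @param edge region edge length in mm (default 5).
#' @param niche_shape \code{"box_pit"}, \code{"hemispherical"} or
#'   \code{"saddle_floor"}.
#' @param niche_dims c(width_y, width_z, depth_x) of the cavity in mm.
#' @param hv_air,hv_soft,hv_fluid,hv_bone class intensity centres
#'   (defaults -1000, 0, 50, 1500; fluid deliberately close to soft tissue
#'   so the histogram model sees one middle peak).
#' @param noise_sigma Gaussian intensity noise (default 100).
#' @param seed RNG seed for the noise (default 0).
#' @param mouth the niche's connection to the middle ear beyond the
#'   region: \code{"drain"} (default) a narrow air channel from the cavity
#'   to the +x face, \code{"sealed"} a cavity fully enclosed in bone, or
#'   \code{"flush"} (box_pit only) cavity walls extended to the +x face.
#' @param saddle_amplitude corner offset of the saddle floor in mm (used
#'   by \code{"saddle_floor"}; default 0.15).
#' @param duct_radius radius of the fluid duct in mm (default 0.7 times
#'   the smaller cavity half-width, keeping the duct inside the membrane
#'   oval).
#' @param drain_width edge of the square drain channel cross-section, mm
#'   (default 0.16, two voxels at the native resolution).
#' @param soft_margin thickness of the soft-tissue slab at the -y face, mm
#'   (default 1.0).
#' @param air_margin thickness of the middle-ear air slab at the +z face,
#'   mm (default 1.0); it is separated from the niche by bone.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(spacing = 0.08, edge = 5,
                         niche_shape = c("box_pit", "hemispherical",
                                         "saddle_floor"),
                         niche_dims = c(1.5, 1.5, 1.0),
                         hv_air = -1000, hv_soft = 0, hv_fluid = 50,
                         hv_bone = 1500, noise_sigma = 100, seed = 0L,
                         mouth = c("drain", "sealed", "flush"),
                         saddle_amplitude = 0.15, duct_radius = NULL,
                         drain_width = 0.16, soft_margin = 1.0,
                         air_margin = 1.0) {
  niche_shape <- match.arg(niche_shape)
  mouth <- match.arg(mouth)
  stopifnot(spacing > 0, edge > 0, length(niche_dims) == 3L,
            all(niche_dims > 0), noise_sigma >= 0)
  if (!(hv_air < hv_soft && hv_soft <= hv_fluid && hv_fluid < hv_bone))
    stop("need hv_air < hv_soft <= hv_fluid < hv_bone", call. = FALSE)
  if (any(niche_dims > edge * 0.9))
    stop("niche dimensions do not fit inside the region", call. = FALSE)
  if (mouth == "flush" && niche_shape != "box_pit")
    stop("mouth = \"flush\" is only supported for the box_pit shape",
         call. = FALSE)
  if (is.null(duct_radius))
    duct_radius <- 0.7 * min(niche_dims[1:2]) / 2
  structure(list(spacing = spacing, edge = edge, niche_shape = niche_shape,
                 niche_dims = niche_dims, hv_air = hv_air,
                 hv_soft = hv_soft, hv_fluid = hv_fluid, hv_bone = hv_bone,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 mouth = mouth, saddle_amplitude = saddle_amplitude,
                 duct_radius = duct_radius, drain_width = drain_width,
                 soft_margin = soft_margin, air_margin = air_margin),
            class = "phantom_spec")
}

#' Generate a phantom volume with ground truth
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return an object of class \code{phantom_truth}: \code{volume}
#'   (a \code{\link{volume_image}}), logical truth masks
#'   \code{bone_truth}, \code{niche_truth}, \code{cochlea_truth},
#'   \code{fiducials}, the true membrane patch \code{membrane_truth} and
#'   the generating \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$spacing
  n <- max(8L, as.integer(round(spec$edge / s)))
  half <- n * s / 2
  origin <- rep(-half + s / 2, 3L)
  ax <- origin[1L] + (seq_len(n) - 1L) * s
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))
  wy <- spec$niche_dims[1L] / 2; wz <- spec$niche_dims[2L] / 2
  depth <- spec$niche_dims[3L]
  # membrane floor surface x_s(y,z)
  xs <- if (spec$niche_shape == "saddle_floor")
    spec$saddle_amplitude * (Y / wy) * (Z / wz) else 0
  top <- if (spec$mouth == "flush") Inf else depth
  cavity <- switch(spec$niche_shape,
    box_pit = abs(Y) < wy & abs(Z) < wz & X > 0 & X < top,
    saddle_floor = abs(Y) < wy & abs(Z) < wz & X > xs & X < top,
    hemispherical = X > 0 & (X^2 + Y^2 + Z^2) < min(wy, wz)^2)
  niche_truth <- cavity & X < depth
  if (spec$mouth == "drain") {
    dw <- spec$drain_width / 2
    cavity <- cavity | (abs(Y) < dw & abs(Z) < dw & X > 0)
  }
  duct <- (Y^2 + Z^2) < spec$duct_radius^2 & X < xs & !cavity
  air_slab <- Z > (half - spec$air_margin) & !cavity & !duct
  soft <- Y < (-half + spec$soft_margin) & !cavity & !duct & !air_slab
  bone_truth <- !cavity & !duct & !air_slab & !soft
  hv <- array(spec$hv_bone, dim = c(n, n, n))
  hv[cavity | air_slab] <- spec$hv_air
  hv[duct] <- spec$hv_fluid
  hv[soft] <- spec$hv_soft
  set.seed(spec$seed)
  if (spec$noise_sigma > 0)
    hv <- hv + array(stats::rnorm(n^3, sd = spec$noise_sigma),
                     dim = c(n, n, n))
  vol <- volume_image(hv, rep(s, 3L), origin)
  fids <- cochlear_fiducials(apex = c(-1.8, 0, 1.2),
                             basal = c(-1.8, 0, -1.0),
                             rw_center = c(0, 0, 0))
  amp <- if (spec$niche_shape == "saddle_floor") spec$saddle_amplitude else 0
  hy <- if (spec$niche_shape == "hemispherical") min(wy, wz) else wy
  hz <- if (spec$niche_shape == "hemispherical") min(wy, wz) else wz
  # circumscribed oval: the whole rectangular cavity floor is membrane
  membrane <- rwm_patch(c(+amp, -hy, -hz), c(-amp, +hy, -hz),
                        c(-amp, -hy, +hz), c(+amp, +hy, +hz),
                        oval_semi_axes = c(sqrt(2) / 2, sqrt(2) / 2))
  structure(list(volume = vol, bone_truth = bone_truth,
                 niche_truth = niche_truth, cochlea_truth = duct,
                 fiducials = fids, membrane_truth = membrane, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", paste(dim(x$volume$data), collapse = " x "),
      " @ ", x$spec$spacing, " mm, shape ", x$spec$niche_shape,
      ", niche ", sum(x$niche_truth), " voxels\n", sep = "")
  invisible(x)
}

#' Downsample a phantom to an intraoperative scanner resolution
#'
#' Area-weighted box filtering (mean-preserving away from borders) to the
#' coarser target spacing; the ground truth stays at native resolution.
#' Optionally adds scanner noise after downsampling: box averaging alone
#' suppresses the native noise by the cube root of the volume ratio,
#' whereas a real scanner contributes its own noise floor at its working
#' resolution.
#'
#' @param gt a \code{\link{generate_phantom}} result (or a
#'   \code{volume_image}).
#' @param target_spacing coarse spacing in mm, >= the native spacing.
#' @param noise_sigma Gaussian scanner noise added after downsampling
#'   (intensity units; default 0, keeping the filter exactly
#'   mean-preserving).
#' @param seed RNG seed for the scanner noise.
#' @return a \code{\link{volume_image}} at the target spacing.
#' @export
degrade_to_clinical <- function(gt, target_spacing, noise_sigma = 0,
                                seed = 0L) {
  vol <- if (inherits(gt, "phantom_truth")) gt$volume else gt
  stopifnot(is_volume_image(vol))
  s <- vol$spacing
  if (any(target_spacing < s - 1e-12))
    stop("`target_spacing` must not be finer than the native spacing",
         call. = FALSE)
  if (all(abs(target_spacing - s) < 1e-12)) return(vol)
  d <- dim(vol$data)
  W <- lapply(1:3, function(a) {
    nf <- d[a]; sf <- s[a]
    nc <- max(1L, as.integer(floor(nf * sf / target_spacing + 1e-9)))
    m <- matrix(0, nc, nf)
    for (j in seq_len(nc)) {
      lo <- (j - 1L) * target_spacing; hi <- j * target_spacing
      i <- seq_len(nf)
      ov <- pmax(0, pmin(hi, i * sf) - pmax(lo, (i - 1L) * sf))
      m[j, ] <- ov / sum(ov)
    }
    m
  })
  contract <- function(dat, M, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(dat, perm)
    da <- dim(a)
    m <- M %*% matrix(a, da[1L])
    dim(m) <- c(nrow(M), da[2L], da[3L])
    aperm(m, order(perm))
  }
  dat <- vol$data
  for (a in 1:3) dat <- contract(dat, W[[a]], a)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    dat <- dat + array(stats::rnorm(length(dat), sd = noise_sigma),
                       dim = dim(dat))
  }
  new_origin <- vol$origin + drop(vol$orientation %*%
                                    (-s / 2 + target_spacing / 2))
  volume_image(dat, rep(target_spacing, 3L), new_origin, vol$orientation)
}

#' Emulate a manual over-segmentation of the niche
#'
#' Dilates the true niche by a Chebyshev radius and optionally roughens the
#' boundary by randomly including half of the next dilation shell,
#' emulating the typical manual over-segmentation used for metric and
#' rule-attribution tests.  The output always contains the truth.
#'
#' @param gt a \code{\link{generate_phantom}} result.
#' @param dilation_voxels integer dilation radius >= 0.
#' @param seed RNG seed for the boundary roughness.
#' @param roughness logical; add the randomised boundary shell?
#' @return logical mask.
#' @export
make_oversegmentation <- function(gt, dilation_voxels = 2L, seed = 0L,
                                  roughness = TRUE) {
  stopifnot(inherits(gt, "phantom_truth"), dilation_voxels >= 0)
  m <- gt$niche_truth
  for (i in seq_len(dilation_voxels)) m <- dilate26(m)
  if (roughness) {
    shell <- dilate26(m) & !m
    set.seed(as.integer(seed))
    pick <- array(stats::runif(length(shell)) < 0.5, dim = dim(shell))
    m <- m | (shell & pick)
  }
  m
}

# one 26-neighbourhood binary dilation via index shifts
dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xi <- pmin(pmax(seq_len(d[1L]) + dx, 1L), d[1L])
    yi <- pmin(pmax(seq_len(d[2L]) + dy, 1L), d[2L])
    zi <- pmin(pmax(seq_len(d[3L]) + dz, 1L), d[3L])
    out <- out | m[xi, yi, zi]
  }
  out
}

#' Write a phantom with its ground truth to a directory
#'
#' Writes \code{volume.nrrd}, truth label NRRDs, fiducials and membrane
#' control points as Slicer markups JSON.
#'
#' @param gt a \code{\link{generate_phantom}} result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_phantom <- function(gt, dir) {
  stopifnot(inherits(gt, "phantom_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nrrd(gt$volume, file.path(dir, "volume.nrrd"))
  geom <- gt$volume
  for (nm in c("bone_truth", "niche_truth", "cochlea_truth")) {
    lab <- volume_image(gt[[nm]] + 0, geom$spacing, geom$origin,
                        geom$orientation)
    write_nrrd(lab, file.path(dir, paste0(nm, ".nrrd")), type = "short")
  }
  write_markup_points(list(apex = gt$fiducials$apex,
                           basal = gt$fiducials$basal,
                           rw_center = gt$fiducials$rw_center),
                      file.path(dir, "fiducials.mrk.json"))
  write_membrane_points(gt$membrane_truth,
                        file.path(dir, "membrane.mrk.json"))
  invisible(dir)
}
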