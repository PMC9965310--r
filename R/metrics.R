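# Comparison quantities for pairs of niche segmentations: volume, membrane
# contact area, Dice and Jaccard overlap, and the attribution of
# manual-vs-semi-automated differences to the individual niche rules.

#' Niche volume of a mask
#'
#' Voxel count times voxel volume, computed on the implant body before any
#' handle is added.
#'
#' @param mask logical array (or a \code{niche_segmentation}).
#' @param vol a \code{\link{volume_image}} (or anything carrying
#'   \code{spacing}) for the voxel size; unused when \code{mask} is a
#'   segmentation.
#' @return volume in mm^3.
#' @export
niche_volume <- function(mask, vol = NULL) {
  if (inherits(mask, "niche_segmentation"))
    return(sum(mask$mask) * prod(mask$spacing))
  stopifnot(!is.null(vol))
  sum(mask) * prod(vol$spacing)
}

#' Membrane contact area of a segmentation
#'
#' Counts kept voxels having at least one face neighbour on the cochlea
#' side of the membrane (the contact surface between niche and scala
#' tympani) and multiplies by the mean voxel face area (spacing^2 on
#' isotropic grids).
#'
#' @param seg a \code{niche_segmentation} or logical mask.
#' @param patch a \code{\link{rwm_patch}}.
#' @param frame a \code{\link{fit_ccs}} frame.
#' @param vol the working-region \code{\link{volume_image}}.
#' @param side optional precomputed side labels.
#' @param count_faces if \code{TRUE}, count cochlea-facing faces instead of
#'   contact voxels (sensitivity alternative).
#' @return area in mm^2.
#' @export
rwm_area <- function(seg, patch, frame, vol, side = NULL,
                     count_faces = FALSE) {
  mask <- if (inherits(seg, "niche_segmentation")) seg$mask else seg
  d <- dim(mask)
  stopifnot(all(dim(vol$data) == d))
  if (is.null(side))
    side <- classify_side(patch, frame, voxel_centers_world(vol))
  coch <- array(side == "cochlea", dim = d)
  shift <- function(a, axis, by) {
    idx <- seq_len(d[axis]) + by
    pad <- idx < 1L | idx > d[axis]
    idx[pad] <- 1L
    out <- switch(axis,
      a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE])
    if (any(pad)) {
      if (axis == 1L) out[pad, , ] <- FALSE
      if (axis == 2L) out[, pad, ] <- FALSE
      if (axis == 3L) out[, , pad] <- FALSE
    }
    out
  }
  nfaces <- array(0L, dim = d)
  for (axis in 1:3) for (by in c(-1L, 1L))
    nfaces <- nfaces + (shift(coch, axis, by) & mask)
  s <- vol$spacing
  face_area <- mean(c(s[1L] * s[2L], s[1L] * s[3L], s[2L] * s[3L]))
  if (count_faces) sum(nfaces[mask]) * face_area
  else sum(nfaces > 0L & mask) * face_area
}

#' Dice and Jaccard overlap of two masks
#'
#' @param a,b logical arrays on the same grid.
#' @return list with \code{dsc} = 2|a n b| / (|a|+|b|) and \code{jaccard}
#'   = |a n b| / |a u b|.
#' @export
overlap <- function(a, b) {
  if (inherits(a, "niche_segmentation")) a <- a$mask
  if (inherits(b, "niche_segmentation")) b <- b$mask
  stopifnot(all(dim(a) == dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L)
    stop("overlap of two empty masks is undefined", call. = FALSE)
  ni <- sum(a & b)
  list(dsc = 2 * ni / (na + nb), jaccard = ni / (na + nb - ni))
}

#' Attribute manual-vs-semi-automated differences to the niche rules
#'
#' Applies the three exclusion rules (inside cochlea / bone / above level)
#' to a manual segmentation and reports the fraction of its voxels removed
#' by each rule alone and by all rules combined; optionally also the
#' residual volume difference of the rule-filtered manual mask relative to
#' the semi-automated mask, \code{(V_semi - V_filtered) / V_semi}.
#'
#' @param manual logical array, the manual segmentation on the working
#'   grid (non-empty).
#' @param bone,patch,frame,level_params,vol,side as in
#'   \code{\link{apply_niche_rules}}.
#' @param semi optional semi-automated \code{niche_segmentation} or mask
#'   for the residual comparison.
#' @return list with \code{fractions} (step1, step2, step3, all),
#'   \code{removed} counts, surviving masks, and \code{residual_vs_semi}
#'   (NA without \code{semi}).
#' @export
rule_attribution <- function(manual, bone, patch, frame, level_params, vol,
                             semi = NULL, side = NULL) {
  if (inherits(manual, "niche_segmentation")) manual <- manual$mask
  if (sum(manual) == 0L)
    stop("manual mask is empty", call. = FALSE)
  rules <- apply_niche_rules(manual, bone, patch, frame, level_params, vol,
                             side)
  n <- sum(manual)
  fractions <- rules$removed / n
  residual <- NA_real_
  if (!is.null(semi)) {
    if (inherits(semi, "niche_segmentation")) semi <- semi$mask
    vs <- sum(semi); vf <- sum(rules$all)
    residual <- (vs - vf) / vs
  }
  list(fractions = fractions, removed = rules$removed,
       masks = rules[c("step1", "step2", "step3", "all")],
       residual_vs_semi = residual)
}

#' Full overlap report for a pair of segmentations
#'
#' Bundles the comparison quantities for segmentations a (e.g. manual) and
#' b (e.g. semi-automated): volumes, intersection volume, Dice, Jaccard,
#' membrane contact areas, and rule-removal fractions of a.
#'
#' @param a,b masks or \code{niche_segmentation}s on the working grid.
#' @param patch,frame,vol,side as in \code{\link{rwm_area}}.
#' @param level_params a \code{\link{fill_parameters}} for the rule
#'   attribution (numeric level).
#' @return an object of class \code{overlap_report}.
#' @export
overlap_report <- function(a, b, patch, frame, vol, level_params,
                           bone, side = NULL) {
  ma <- if (inherits(a, "niche_segmentation")) a$mask else a
  mb <- if (inherits(b, "niche_segmentation")) b$mask else b
  ov <- overlap(ma, mb)
  attr_a <- rule_attribution(ma, bone, patch, frame, level_params, vol,
                             semi = mb, side = side)
  rep <- list(
    volume_a = niche_volume(ma, vol), volume_b = niche_volume(mb, vol),
    intersection_volume = sum(ma & mb) * prod(vol$spacing),
    dsc = ov$dsc, jaccard = ov$jaccard,
    rwm_area_a = rwm_area(ma, patch, frame, vol, side = side),
    rwm_area_b = rwm_area(mb, patch, frame, vol, side = side),
    rule_removals = attr_a$fractions,
    residual_vs_semi = attr_a$residual_vs_semi)
  stopifnot(abs(rep$jaccard - rep$dsc / (2 - rep$dsc)) < 1e-12,
            rep$intersection_volume <= min(rep$volume_a, rep$volume_b) +
              1e-9)
  structure(rep, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n",
      sprintf("  volumes: a %.4g, b %.4g, intersection %.4g mm^3\n",
              x$volume_a, x$volume_b, x$intersection_volume),
      sprintf("  DSC %.4f, Jaccard %.4f\n", x$dsc, x$jaccard),
      sprintf("  RWM contact area: a %.4g, b %.4g mm^2\n",
              x$rwm_area_a, x$rwm_area_b),
      "  rule removal fractions of a: ",
      paste(names(x$rule_removals),
            sprintf("%.1f%%", 100 * x$rule_removals),
            sep = " ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an overlap report as JSON
#' @param report an \code{overlap_report}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
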