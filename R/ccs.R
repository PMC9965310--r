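# Cochlear coordinate system (CCS): an orthonormal frame fitted from three
# anatomical fiducials.  z runs along the modiolar axis toward the
# helicotrema, x points from the modiolar axis to the round window membrane,
# and the origin sits at the RWM centre so that implant geometry can be
# expressed in anatomical directions.

#' Cochlear fiducials
#'
#' @param apex world point (mm) at the midmodiolar apex.
#' @param basal world point (mm) at the midmodiolar basal turn.
#' @param rw_center world point (mm) at the round window centre.
#' @return an object of class \code{cochlear_fiducials}.
#' @export
cochlear_fiducials <- function(apex, basal, rw_center) {
  apex <- as.numeric(apex); basal <- as.numeric(basal)
  rw_center <- as.numeric(rw_center)
  stopifnot(length(apex) == 3L, length(basal) == 3L, length(rw_center) == 3L)
  if (sqrt(sum((apex - basal)^2)) < 1e-9)
    stop("apex and basal fiducials coincide", call. = FALSE)
  structure(list(apex = apex, basal = basal, rw_center = rw_center),
            class = "cochlear_fiducials")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

normalize <- function(v) v / sqrt(sum(v^2))

#' Fit the cochlear coordinate system from three fiducials
#'
#' The z axis is the unit vector from the basal-turn fiducial to the apex
#' (the modiolar axis toward the helicotrema).  The x axis points from the
#' modiolar line to the round window centre (the component of
#' \code{rw_center} orthogonal to z), and the origin is shifted to the RWM
#' centre.  y completes a right-handed frame, \code{y = z x x}; for left
#' ears (\code{side = "left"}) y is mirrored so that "toward the basal
#' turn" keeps its anatomical meaning.
#'
#' @param fids a \code{\link{cochlear_fiducials}}.
#' @param side working orientation, \code{"right"} (default) or
#'   \code{"left"}.
#' @return an object of class \code{ccs_frame} with fields \code{origin},
#'   \code{x_axis}, \code{y_axis}, \code{z_axis}.
#' @export
fit_ccs <- function(fids, side = c("right", "left")) {
  stopifnot(inherits(fids, "cochlear_fiducials"))
  side <- match.arg(side)
  z <- normalize(fids$apex - fids$basal)
  v <- fids$rw_center - fids$basal
  perp <- v - sum(v * z) * z
  if (sqrt(sum(perp^2)) < 1e-9)
    stop("round window centre lies on the modiolar line; ",
         "cannot orient the x axis", call. = FALSE)
  x <- normalize(perp)
  y <- cross3(z, x)
  if (side == "left") y <- -y
  structure(list(origin = fids$rw_center, x_axis = x, y_axis = y, z_axis = z,
                 side = side),
            class = "ccs_frame")
}

#' @export
print.ccs_frame <- function(x, ...) {
  cat("<ccs_frame> origin (", paste(signif(x$origin, 4), collapse = ", "),
      ") mm, side ", x$side, "\n", sep = "")
  invisible(x)
}

#' Transform points between world and cochlear coordinates
#'
#' @param frame a \code{\link{fit_ccs}} frame.
#' @param points n x 3 matrix (or length-3 vector) of points.
#' @param direction \code{"to_ccs"} maps world points into the frame;
#'   \code{"from_ccs"} is its exact inverse.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(frame, points, direction = c("to_ccs",
                                                          "from_ccs")) {
  stopifnot(inherits(frame, "ccs_frame"))
  direction <- match.arg(direction)
  pts <- matrix(as.numeric(points), ncol = 3L)
  rot <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  if (direction == "to_ccs") {
    sweep(pts, 2L, frame$origin, "-") %*% rot
  } else {
    sweep(pts %*% t(rot), 2L, frame$origin, "+")
  }
}

#' Read cochlear fiducials from a markups JSON or CSV file
#'
#' Accepts 3D Slicer markups JSON (\code{.mrk.json}; the
#' \code{coordinateSystem} field is honoured, RAS converted to LPS) or a
#' plain CSV with columns \code{name,x,y,z} in LPS mm.  Point names
#' \code{"apex"}, \code{"basal"} and \code{"rw_center"} are required.
#'
#' @param path input file.
#' @return a \code{\link{cochlear_fiducials}}.
#' @export
read_fiducials <- function(path) {
  pts <- read_markup_points(path)
  need <- c("apex", "basal", "rw_center")
  if (!all(need %in% names(pts)))
    stop("fiducial file must contain points named ",
         paste(need, collapse = ", "), call. = FALSE)
  cochlear_fiducials(pts[["apex"]], pts[["basal"]], pts[["rw_center"]])
}

# Shared parser: named world points from .mrk.json or name,x,y,z CSV.
read_markup_points <- function(path) {
  if (!file.exists(path)) stop("fiducial file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    mk <- doc$markups[[1L]]
    cs <- if (!is.null(mk$coordinateSystem)) mk$coordinateSystem else "LPS"
    flip <- if (toupper(cs) == "RAS") c(-1, -1, 1) else c(1, 1, 1)
    pts <- lapply(mk$controlPoints, function(cp)
      flip * as.numeric(unlist(cp$position)))
    names(pts) <- vapply(mk$controlPoints, function(cp) cp$label, "")
    pts
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("name", "x", "y", "z") %in% names(df)))
      stop("fiducial CSV needs columns name,x,y,z", call. = FALSE)
    pts <- lapply(seq_len(nrow(df)), function(i)
      c(df$x[i], df$y[i], df$z[i]))
    names(pts) <- df$name
    pts
  }
}

#' Write named points as a 3D Slicer markups JSON file
#'
#' @param points named list of length-3 world points (LPS mm).
#' @param path output \code{.mrk.json} path.
#' @return \code{path}, invisibly.
#' @export
write_markup_points <- function(points, path) {
  cps <- lapply(seq_along(points), function(i) {
    list(id = as.character(i), label = names(points)[i],
         position = as.numeric(points[[i]]))
  })
  doc <- list(markups = list(list(
    type = "Fiducial", coordinateSystem = "LPS", controlPoints = cps)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
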