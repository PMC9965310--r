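# Round window membrane model: an oval cut-out of a bilinear "saddle"
# surface spanned by four control points.  The patch partitions the working
# region into a cochlea side and a middle-ear side; the implant body may
# only occupy the middle-ear side.

#' Bilinear membrane patch
#'
#' The surface is \eqn{S(u,v) = (1-u)(1-v)p00 + u(1-v)p10 + (1-u)v p01 +
#' uv p11} for \eqn{u,v \in [0,1]}; the membrane proper is the oval
#' \eqn{((u-1/2)/a)^2 + ((v-1/2)/b)^2 \le 1} cut out of it.
#'
#' @param p00,p10,p01,p11 world control points (mm).
#' @param oval_semi_axes semi-axes (a, b) of the oval in the (u, v)
#'   parameter plane; default \code{c(0.5, 0.5)}, the ellipse inscribed in
#'   the unit parameter square.
#' @return an object of class \code{rwm_patch}.
#' @export
rwm_patch <- function(p00, p10, p01, p11, oval_semi_axes = c(0.5, 0.5)) {
  P <- rbind(as.numeric(p00), as.numeric(p10), as.numeric(p01),
             as.numeric(p11))
  if (ncol(P) != 3L || any(!is.finite(P)))
    stop("control points must be finite length-3 world points", call. = FALSE)
  # collinearity check: rank of the centred point set must be >= 2
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[2L] < 1e-9)
    stop("the four control points are collinear", call. = FALSE)
  ab <- as.numeric(oval_semi_axes)
  if (length(ab) != 2L || any(ab <= 0) || any(ab > 0.5 * sqrt(2) + 1e-12))
    stop("oval semi-axes must lie in (0, sqrt(2)/2]", call. = FALSE)
  structure(list(p00 = P[1L, ], p10 = P[2L, ], p01 = P[3L, ], p11 = P[4L, ],
                 oval_semi_axes = ab),
            class = "rwm_patch")
}

# Coefficients of S(u,v) = a + u b + v c + uv d.
patch_coefs <- function(patch) {
  list(a = patch$p00, b = patch$p10 - patch$p00, c = patch$p01 - patch$p00,
       d = patch$p11 - patch$p10 - patch$p01 + patch$p00)
}

#' Evaluate the bilinear membrane surface
#'
#' @param patch a \code{\link{rwm_patch}}.
#' @param u,v parameter values in \code{[0, 1]} (vectors of equal length are
#'   recycled against each other).
#' @return n x 3 matrix of world points.
#' @export
eval_surface <- function(patch, u, v) {
  stopifnot(inherits(patch, "rwm_patch"))
  if (any(u < -1e-12 | u > 1 + 1e-12) || any(v < -1e-12 | v > 1 + 1e-12))
    stop("u and v must lie in [0, 1]", call. = FALSE)
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  k <- patch_coefs(patch)
  cbind(k$a[1L] + u * k$b[1L] + v * k$c[1L] + u * v * k$d[1L],
        k$a[2L] + u * k$b[2L] + v * k$c[2L] + u * v * k$d[2L],
        k$a[3L] + u * k$b[3L] + v * k$c[3L] + u * v * k$d[3L])
}

#' Mean membrane model
#'
#' Four displacement vectors, in cochlear-frame coordinates, from the round
#' window centre to the patch control points.  The packaged default is the
#' saddle used by the synthetic phantom (half-extent 0.75 mm, saddle
#' amplitude 0.15 mm); site-specific models can be supplied through the
#' pipeline configuration.
#'
#' @param offsets 4 x 3 matrix of CCS offsets (mm), rows in the order
#'   p00, p10, p01, p11.
#' @return an object of class \code{mean_membrane_model}.
#' @export
mean_membrane_model <- function(offsets = default_membrane_offsets()) {
  offsets <- as.matrix(offsets)
  stopifnot(all(dim(offsets) == c(4L, 3L)), all(is.finite(offsets)))
  if (abs(mean(offsets[, 1L])) > 1e-6)
    stop("mean membrane model must be centred on the RWM centre ",
         "(mean x offset must vanish)", call. = FALSE)
  structure(list(offsets = offsets), class = "mean_membrane_model")
}

#' @rdname mean_membrane_model
#' @param half_extent patch half width in mm.
#' @param saddle_amplitude out-of-plane corner offset in mm.
#' @export
default_membrane_offsets <- function(half_extent = 0.75,
                                     saddle_amplitude = 0.15) {
  h <- half_extent; s <- saddle_amplitude
  rbind(c(+s, -h, -h), c(-s, +h, -h), c(-s, -h, +h), c(+s, +h, +h))
}

#' Place the mean membrane model in a cochlear frame
#'
#' @param frame a \code{\link{fit_ccs}} frame.
#' @param model a \code{\link{mean_membrane_model}}.
#' @param oval_semi_axes forwarded to \code{\link{rwm_patch}}.
#' @return a \code{\link{rwm_patch}} whose control points are the model
#'   offsets mapped through the frame; individual fitting is done by
#'   replacing control points afterwards.
#' @export
place_mean_patch <- function(frame, model = mean_membrane_model(),
                             oval_semi_axes = c(0.5, 0.5)) {
  stopifnot(inherits(frame, "ccs_frame"),
            inherits(model, "mean_membrane_model"))
  W <- transform_points(frame, model$offsets, "from_ccs")
  rwm_patch(W[1L, ], W[2L, ], W[3L, ], W[4L, ], oval_semi_axes)
}

#' Project world points onto the (extended) bilinear surface
#'
#' Finds, per point, the parameter pair minimising the distance to the
#' surface, by damped Newton iteration in (u, v) initialised from a 9 x 9
#' grid over the unit square, tolerance 1e-8 in (u, v); points that fail to
#' converge fall back to a dense-grid minimum.  The surface is extended
#' beyond the unit square, so returned parameters may lie outside [0, 1].
#'
#' @param patch a \code{\link{rwm_patch}}.
#' @param points n x 3 matrix of world points.
#' @return list with vectors \code{u}, \code{v}, the foot points
#'   \code{foot} (n x 3) and squared distances \code{dist2}.
#' @export
project_to_patch <- function(patch, points) {
  stopifnot(inherits(patch, "rwm_patch"))
  p <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(p)
  k <- patch_coefs(patch)
  Sfun <- function(u, v)
    cbind(k$a[1L] + u * k$b[1L] + v * k$c[1L] + u * v * k$d[1L],
          k$a[2L] + u * k$b[2L] + v * k$c[2L] + u * v * k$d[2L],
          k$a[3L] + u * k$b[3L] + v * k$c[3L] + u * v * k$d[3L])
  obj <- function(u, v, idx = seq_len(n)) {
    S <- Sfun(u, v)
    (S[, 1L] - p[idx, 1L])^2 + (S[, 2L] - p[idx, 2L])^2 +
      (S[, 3L] - p[idx, 3L])^2
  }
  # 9 x 9 grid initialisation
  g <- seq(0, 1, length.out = 9L)
  bestF <- rep(Inf, n); u <- numeric(n); v <- numeric(n)
  for (gu in g) for (gv in g) {
    F <- obj(rep(gu, n), rep(gv, n))
    upd <- F < bestF
    bestF[upd] <- F[upd]; u[upd] <- gu; v[upd] <- gv
  }
  lambda <- rep(0, n)
  active <- rep(TRUE, n)
  for (it in 1:80) {
    ia <- which(active)
    if (length(ia) == 0L) break
    ua <- u[ia]; va <- v[ia]
    S <- Sfun(ua, va)
    r <- S - p[ia, , drop = FALSE]
    Su <- cbind(k$b[1L] + va * k$d[1L], k$b[2L] + va * k$d[2L],
                k$b[3L] + va * k$d[3L])
    Sv <- cbind(k$c[1L] + ua * k$d[1L], k$c[2L] + ua * k$d[2L],
                k$c[3L] + ua * k$d[3L])
    g1 <- rowSums(Su * r); g2 <- rowSums(Sv * r)
    rd <- r[, 1L] * k$d[1L] + r[, 2L] * k$d[2L] + r[, 3L] * k$d[3L]
    H11 <- rowSums(Su * Su) + lambda[ia]
    H22 <- rowSums(Sv * Sv) + lambda[ia]
    H12 <- rowSums(Su * Sv) + rd
    det <- H11 * H22 - H12^2
    sing <- det < 1e-14 | H11 <= 0
    lambda[ia[sing]] <- pmax(lambda[ia[sing]] * 4, 1e-6)
    ok <- !sing
    io <- ia[ok]
    du <- -(H22[ok] * g1[ok] - H12[ok] * g2[ok]) / det[ok]
    dv <- -(H11[ok] * g2[ok] - H12[ok] * g1[ok]) / det[ok]
    newu <- u[io] + du; newv <- v[io] + dv
    Fnew <- obj(newu, newv, io)
    Fold <- rowSums(r[ok, , drop = FALSE]^2)
    acc <- Fnew <= Fold + 1e-15
    iacc <- io[acc]
    u[iacc] <- newu[acc]; v[iacc] <- newv[acc]
    lambda[iacc] <- lambda[iacc] / 3
    irej <- io[!acc]
    lambda[irej] <- pmax(lambda[irej] * 4, 1e-6)
    conv <- abs(du) < 1e-8 & abs(dv) < 1e-8 & acc
    active[io[conv]] <- FALSE
  }
  # dense-grid fallback for stragglers
  if (any(active)) {
    gg <- seq(-0.5, 1.5, by = 1e-3)
    for (i in which(active)) {
      Fu <- outer(gg, gg, function(uu, vv) {
        S1 <- k$a[1L] + uu * k$b[1L] + vv * k$c[1L] + uu * vv * k$d[1L]
        S2 <- k$a[2L] + uu * k$b[2L] + vv * k$c[2L] + uu * vv * k$d[2L]
        S3 <- k$a[3L] + uu * k$b[3L] + vv * k$c[3L] + uu * vv * k$d[3L]
        (S1 - p[i, 1L])^2 + (S2 - p[i, 2L])^2 + (S3 - p[i, 3L])^2
      })
      w <- arrayInd(which.min(Fu), dim(Fu))
      u[i] <- gg[w[1L]]; v[i] <- gg[w[2L]]
    }
  }
  foot <- Sfun(u, v)
  list(u = u, v = v, foot = foot,
       dist2 = rowSums((foot - p)^2))
}

#' Classify points as cochlea-side or middle-ear-side of the membrane
#'
#' Each point is projected onto the extended bilinear surface; the signed
#' offset along the local surface normal (oriented toward the frame's +x,
#' the middle-ear direction) decides the label.  Points whose projection
#' falls outside the oval cut-out are labelled \code{middle_ear}: the
#' membrane does not bound them.  Boundary ties (|offset| < 1e-9 mm) are
#' labelled \code{middle_ear} so the implant never claims membrane voxels.
#'
#' @param patch a \code{\link{rwm_patch}}.
#' @param frame a \code{\link{fit_ccs}} frame (supplies the middle-ear
#'   direction).
#' @param points n x 3 matrix of world points.
#' @return character vector of labels, \code{"cochlea"} or
#'   \code{"middle_ear"}.
#' @export
classify_side <- function(patch, frame, points) {
  stopifnot(inherits(patch, "rwm_patch"), inherits(frame, "ccs_frame"))
  p <- matrix(as.numeric(points), ncol = 3L)
  k <- patch_coefs(patch)
  # degenerate (zero-area) patch guard: normals at the four corners
  crn <- expand.grid(u = c(0, 1), v = c(0, 1))
  nn <- vapply(seq_len(4L), function(i) {
    su <- k$b + crn$v[i] * k$d; sv <- k$c + crn$u[i] * k$d
    sqrt(sum(cross3(su, sv)^2))
  }, 0)
  if (max(nn) < 1e-12)
    stop("membrane patch has zero area", call. = FALSE)
  pr <- project_to_patch(patch, p)
  r <- p - pr$foot
  Su <- cbind(k$b[1L] + pr$v * k$d[1L], k$b[2L] + pr$v * k$d[2L],
              k$b[3L] + pr$v * k$d[3L])
  Sv <- cbind(k$c[1L] + pr$u * k$d[1L], k$c[2L] + pr$u * k$d[2L],
              k$c[3L] + pr$u * k$d[3L])
  nrm <- cbind(Su[, 2L] * Sv[, 3L] - Su[, 3L] * Sv[, 2L],
               Su[, 3L] * Sv[, 1L] - Su[, 1L] * Sv[, 3L],
               Su[, 1L] * Sv[, 2L] - Su[, 2L] * Sv[, 1L])
  orient <- sign(nrm %*% frame$x_axis)
  orient[orient == 0] <- 1
  signed <- rowSums(r * nrm) * drop(orient) /
    pmax(sqrt(rowSums(nrm^2)), 1e-300)
  ab <- patch$oval_semi_axes
  inside_oval <- ((pr$u - 0.5) / ab[1L])^2 + ((pr$v - 0.5) / ab[2L])^2 <= 1
  ifelse(inside_oval & signed < -1e-9, "cochlea", "middle_ear")
}

#' Read or write membrane control points as Slicer markups JSON
#'
#' Point labels \code{"rwm_00"}, \code{"rwm_10"}, \code{"rwm_01"},
#' \code{"rwm_11"} are used.
#'
#' @param path input/output \code{.mrk.json} file.
#' @param oval_semi_axes forwarded to \code{\link{rwm_patch}} on read.
#' @return \code{read_membrane_points}: a \code{\link{rwm_patch}}.
#' @export
read_membrane_points <- function(path, oval_semi_axes = c(0.5, 0.5)) {
  pts <- read_markup_points(path)
  need <- c("rwm_00", "rwm_10", "rwm_01", "rwm_11")
  if (!all(need %in% names(pts)))
    stop("membrane file must contain points named ",
         paste(need, collapse = ", "), call. = FALSE)
  rwm_patch(pts[["rwm_00"]], pts[["rwm_10"]], pts[["rwm_01"]],
            pts[["rwm_11"]], oval_semi_axes)
}

#' @rdname read_membrane_points
#' @param patch a \code{\link{rwm_patch}} to write.
#' @export
write_membrane_points <- function(patch, path) {
  stopifnot(inherits(patch, "rwm_patch"))
  write_markup_points(list(rwm_00 = patch$p00, rwm_10 = patch$p10,
                           rwm_01 = patch$p01, rwm_11 = patch$p11), path)
}
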