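# Bone thresholding: the working-region histogram of a temporal-bone CBCT
# is tri-modal (air / soft tissue + cochlear fluid / bone).  A three
# component Gaussian mixture is fitted to the intensities and the bone
# threshold is placed at the density minimum between the soft-tissue and
# bone peaks.

#' Gaussian pre-smoothing of a volume
#'
#' Separable Gaussian smoothing with a per-axis standard deviation given in
#' voxels (a width in the order of one voxel is typical for noisy scans).
#' Borders are handled by replication, so a constant volume is preserved
#' exactly.  Width 0 returns the input unchanged.
#'
#' @param vol a \code{\link{volume_image}}.
#' @param kernel_width_voxels Gaussian sigma in voxels, >= 0.
#' @return a \code{volume_image}.
#' @export
smooth_intensities <- function(vol, kernel_width_voxels = 1) {
  stopifnot(is_volume_image(vol))
  s <- kernel_width_voxels
  if (!is.finite(s) || s < 0)
    stop("`kernel_width_voxels` must be >= 0", call. = FALSE)
  if (s == 0) return(vol)
  r <- max(1L, ceiling(4 * s))
  w <- stats::dnorm(-r:r, sd = s)
  w <- w / sum(w)
  dat <- vol$data
  d <- dim(dat)
  for (axis in 1:3) {
    acc <- array(0, dim = d)
    for (j in seq_along(w)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
      acc <- acc + w[j] * switch(axis,
        dat[idx, , , drop = FALSE],
        dat[, idx, , drop = FALSE],
        dat[, , idx, drop = FALSE])
    }
    dat <- acc
  }
  out <- vol
  out$data <- dat
  out
}

#' Three-peak Gaussian mixture model of a working-region histogram
#'
#' @param centers,widths,weights numeric length-3: peak locations, standard
#'   deviations and mixing proportions for (air, soft_tissue, bone).
#'   Centers must be strictly increasing, widths positive, weights in (0,1)
#'   summing to one.
#' @return an object of class \code{intensity_histogram_model}.
#' @export
intensity_histogram_model <- function(centers, widths, weights) {
  centers <- as.numeric(centers); widths <- as.numeric(widths)
  weights <- as.numeric(weights)
  stopifnot(length(centers) == 3L, length(widths) == 3L,
            length(weights) == 3L)
  if (any(diff(centers) <= 0))
    stop("peak centers must be strictly increasing (air, soft_tissue, bone)",
         call. = FALSE)
  if (any(widths <= 0)) stop("peak widths must be positive", call. = FALSE)
  if (any(weights <= 0) || any(weights >= 1) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must lie in (0,1) and sum to 1", call. = FALSE)
  structure(list(centers = centers, widths = widths, weights = weights),
            class = "intensity_histogram_model")
}

#' @export
print.intensity_histogram_model <- function(x, ...) {
  cat("<intensity_histogram_model>\n")
  m <- rbind(center = x$centers, width = x$widths, weight = x$weights)
  colnames(m) <- c("air", "soft_tissue", "bone")
  print(signif(m, 5))
  invisible(x)
}

mixture_density <- function(model, x) {
  d <- 0
  for (j in 1:3)
    d <- d + model$weights[j] *
      stats::dnorm(x, model$centers[j], model$widths[j])
  d
}

#' Fit air / soft-tissue / bone peaks to the ROI intensity histogram
#'
#' A three-component 1-D Gaussian mixture is fitted by EM to a subsample of
#' at most 2e5 voxel intensities.  Components are initialised at the three
#' most prominent histogram modes and relabelled in ascending centre order
#' as air, soft_tissue, bone.  A uniform background component is carried
#' through the EM to absorb partial-volume voxels that belong to no tissue
#' peak (they would otherwise inflate the soft-tissue width at coarse
#' resolutions); its weight is reported as the \code{background} attribute
#' and the three peak weights are renormalised.
#'
#' @param vol a \code{\link{volume_image}} (the working ROI).
#' @param seed integer seed controlling the subsample and the k-means
#'   initialisation (default 0).
#' @param max_sample subsample cap (default 2e5 intensities).
#' @return an \code{\link{intensity_histogram_model}}.
#' @export
fit_histogram_peaks <- function(vol, seed = 0L, max_sample = 2e5) {
  stopifnot(is_volume_image(vol))
  x <- as.vector(vol$data)
  if (length(unique(x)) < 3L)
    stop("histogram fit needs at least 3 distinct intensity values",
         call. = FALSE)
  set.seed(as.integer(seed))
  if (length(x) > max_sample)
    x <- x[sample.int(length(x), max_sample)]
  # initialise at the three most prominent histogram peaks; percentile or
  # random starts are unreliable when one tissue class dominates the region
  init <- histogram_peak_init(x)
  mu <- init$mu; sg <- init$sg; wt <- init$wt
  # uniform background over the intensity range catches partial-volume
  # voxels that belong to no peak
  u_dens <- 1 / max(diff(range(x)), 1e-12)
  w_bg <- 0.05
  wt <- wt * (1 - w_bg)
  loglik_old <- -Inf
  for (it in 1:500) {
    dens <- vapply(1:3, function(j)
      wt[j] * stats::dnorm(x, mu[j], sg[j]), numeric(length(x)))
    bg <- w_bg * u_dens
    tot <- rowSums(dens) + bg
    tot[tot < 1e-300] <- 1e-300
    loglik <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk / length(x) < 1e-4))
      stop("histogram fit degenerated (vanishing component); ",
           "set the bone threshold manually", call. = FALSE)
    wt <- nk / length(x)
    w_bg <- max(1 - sum(wt), 0)
    mu <- colSums(resp * x) / nk
    sg <- sqrt(vapply(1:3, function(j)
      sum(resp[, j] * (x - mu[j])^2), 0) / nk)
    sg[sg < 1e-9] <- 1e-9
    if (is.finite(loglik_old) &&
        abs(loglik - loglik_old) < 1e-8 * abs(loglik)) break
    loglik_old <- loglik
  }
  ord <- order(mu)
  out <- intensity_histogram_model(mu[ord], sg[ord], wt[ord] / sum(wt))
  attr(out, "background") <- w_bg
  out
}

# Deterministic EM starting values: pick the three highest smoothed
# histogram modes subject to a minimum separation, falling back to
# quantiles if fewer than three modes stand out.
histogram_peak_init <- function(x, nbins = 256L) {
  rng <- range(x)
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- hist(x, breaks = br, plot = FALSE)
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / 5, 5L), sides = 2L))
  cnt[is.na(cnt)] <- 0
  mid <- h$mids
  sep <- diff(rng) / 16
  # candidate modes: strict local maxima of the smoothed counts
  n <- length(cnt)
  is_mode <- cnt > 0 &
    cnt >= c(-Inf, cnt[-n]) & cnt >= c(cnt[-1L], -Inf) &
    cnt >= c(-Inf, -Inf, cnt[-c(n - 1L, n)]) &
    cnt >= c(cnt[-c(1L, 2L)], -Inf, -Inf)
  peaks <- numeric(0)
  ord <- order(cnt, decreasing = TRUE)
  for (i in ord) {
    if (!is_mode[i]) next
    if (length(peaks) == 3L) break
    if (all(abs(mid[i] - peaks) >= sep)) peaks <- c(peaks, mid[i])
  }
  mu <- if (length(peaks) == 3L) sort(peaks)
    else as.numeric(stats::quantile(x, c(0.1, 0.5, 0.9)))
  grp <- max.col(-abs(outer(x, mu, "-")), ties.method = "first")
  sg <- vapply(1:3, function(j) stats::sd(x[grp == j]), 0)
  # floor at the bin width: mode positions are quantised to bins, so the
  # initial component must be wide enough to reach its own data
  binw <- diff(rng) / nbins
  sg[!is.finite(sg)] <- binw
  sg <- pmax(sg, binw)
  wt <- tabulate(grp, 3L) / length(x)
  wt <- pmax(wt, 1e-3); wt <- wt / sum(wt)
  list(mu = mu, sg = sg, wt = wt)
}

#' Bone threshold
#'
#' @param value threshold intensity.
#' @param source \code{"automatic"} or \code{"user"}.
#' @return an object of class \code{bone_threshold}.
#' @export
bone_threshold <- function(value, source = c("user", "automatic")) {
  source <- match.arg(source)
  stopifnot(is.finite(value))
  structure(list(value = as.numeric(value), source = source),
            class = "bone_threshold")
}

#' Estimate the bone threshold from a fitted histogram model
#'
#' The threshold is the intensity minimising the mixture density between the
#' soft-tissue and bone centres (the misclassification-minimising boundary
#' under the fitted model); if no interior minimum exists the midpoint of
#' the two centres is used.
#'
#' @param model an \code{\link{intensity_histogram_model}}.
#' @return a \code{\link{bone_threshold}} with source \code{"automatic"}.
#' @export
estimate_bone_threshold <- function(model) {
  stopifnot(inherits(model, "intensity_histogram_model"))
  lo <- model$centers[2L]; hi <- model$centers[3L]
  opt <- stats::optimize(function(x) mixture_density(model, x),
                         interval = c(lo, hi), tol = 1e-8 * (hi - lo))
  x <- opt$minimum
  eps <- 1e-4 * (hi - lo)
  interior <- x > lo + eps && x < hi - eps &&
    opt$objective < mixture_density(model, lo) &&
    opt$objective < mixture_density(model, hi)
  if (!interior) x <- (lo + hi) / 2
  bone_threshold(x, "automatic")
}

#' Threshold a volume into a bone mask
#'
#' @param vol a \code{\link{volume_image}}.
#' @param t a \code{\link{bone_threshold}} or a bare number.
#' @return logical 3D array, \code{TRUE} where intensity >= threshold (bone
#'   inclusive, conservative toward bone).
#' @export
bone_mask <- function(vol, t) {
  stopifnot(is_volume_image(vol))
  tv <- if (inherits(t, "bone_threshold")) t$value else as.numeric(t)
  vol$data >= tv
}
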