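# Bilinear membrane patch: surface evaluation, mean-model placement, and
# cochlea / middle-ear side classification against a grid-search oracle.

canonical_saddle <- function()
  rwm_patch(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))

test_that("eval_surface reproduces corners and the bilinear midpoint", {
  p <- canonical_saddle()
  expect_equal(eval_surface(p, 0, 0)[1, ], p$p00)
  expect_equal(eval_surface(p, 1, 1)[1, ], p$p11)
  expect_equal(eval_surface(p, 1, 0)[1, ], p$p10)
  expect_equal(eval_surface(p, 0, 1)[1, ], p$p01)
  expect_equal(eval_surface(p, 0.5, 0.5)[1, ], c(0.5, 0.5, 0.25))
  m <- (p$p00 + p$p10 + p$p01 + p$p11) / 4
  expect_equal(eval_surface(p, 0.5, 0.5)[1, ], m)
  expect_error(eval_surface(p, 1.2, 0.5), "0, 1")
})

test_that("patch constructor validates geometry", {
  expect_error(rwm_patch(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "collinear")
  expect_error(rwm_patch(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                         oval_semi_axes = c(0.9, 0.5)), "semi-axes")
})

test_that("mean model placement is rigid and centred on the RWM center", {
  model <- mean_membrane_model()
  id <- fit_ccs(cochlear_fiducials(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0.5)))
  # identity-like frame at origin shifted to rw: origin = rw_center
  patch <- place_mean_patch(id, model)
  ctr <- (patch$p00 + patch$p10 + patch$p01 + patch$p11) / 4
  off <- colMeans(model$offsets)
  expect_lt(sqrt(sum((ctr - id$origin)^2)), sqrt(sum(off^2)) + 1e-9)
  # translation equivariance
  fids2 <- cochlear_fiducials(c(5, -2, 4), c(5, -2, 3), c(6, -2, 3.5))
  fr2 <- fit_ccs(fids2)
  p2 <- place_mean_patch(fr2, model)
  d <- fids2$rw_center - id$origin
  expect_world_equal(p2$p00, patch$p00 + d)
  expect_world_equal(p2$p11, patch$p11 + d)
  # mean model with nonzero mean x offset is invalid
  expect_error(mean_membrane_model(matrix(1, 4, 3)), "x offset")
})

test_that("planar patch side labels equal the analytic plane test", {
  fr <- fit_ccs(cochlear_fiducials(c(0, 0, 4), c(0, 0, 0), c(3, 0, 1)))
  pp <- rwm_patch(c(0, -1, -1), c(0, 1, -1), c(0, -1, 1), c(0, 1, 1),
                  oval_semi_axes = c(0.5 * sqrt(2), 0.5 * sqrt(2)))
  set.seed(21)
  pts <- cbind(runif(400, -1, 1), runif(400, -0.6, 0.6),
               runif(400, -0.6, 0.6))
  lab <- classify_side(pp, fr, pts)
  # oval circumscribes the square, so every projection inside the patch
  # is inside the oval: labels must match the sign of x exactly
  expect_identical(lab, ifelse(pts[, 1] < -1e-9, "cochlea", "middle_ear"))
  # points exactly on the surface take the middle_ear tie label
  on <- cbind(0, c(0, 0.3), c(0, -0.2))
  expect_identical(classify_side(pp, fr, on),
                   c("middle_ear", "middle_ear"))
})

test_that("projection outside the oval cut-out labels middle_ear", {
  fr <- fit_ccs(cochlear_fiducials(c(0, 0, 4), c(0, 0, 0), c(3, 0, 1)))
  pp <- rwm_patch(c(0, -1, -1), c(0, 1, -1), c(0, -1, 1), c(0, 1, 1))
  # (u,v) = (0.98, 0.98): inside the unit square, outside the inscribed oval
  p_out <- c(-0.5, 0.96, 0.96)
  p_in <- c(-0.5, 0, 0)
  expect_identical(classify_side(pp, fr, rbind(p_out, p_in)),
                   c("middle_ear", "cochlea"))
})

test_that("classify_side matches a dense grid projection oracle", {
  set.seed(22)
  fr <- fit_ccs(cochlear_fiducials(c(0, 0, 4), c(0, 0, 0), c(3, 0, 1)))
  patch <- rwm_patch(c(0.3, -1, -1), c(-0.25, 1, -1), c(-0.35, -1, 1),
                     c(0.28, 1, 1.1))
  n <- 1000
  pts <- cbind(runif(n, -1, 1), runif(n, -1.4, 1.4), runif(n, -1.4, 1.4))
  lab <- classify_side(patch, fr, pts)
  # oracle: nearest surface point on an extended (u,v) grid refined to
  # step 1e-3 (coarse scan + local dense refinement, no Newton involved)
  k <- list(a = patch$p00, b = patch$p10 - patch$p00,
            c = patch$p01 - patch$p00,
            d = patch$p11 - patch$p10 - patch$p01 + patch$p00)
  Sgrid <- function(uu, vv)
    cbind(k$a[1] + uu * k$b[1] + vv * k$c[1] + uu * vv * k$d[1],
          k$a[2] + uu * k$b[2] + vv * k$c[2] + uu * vv * k$d[2],
          k$a[3] + uu * k$b[3] + vv * k$c[3] + uu * vv * k$d[3])
  cg <- seq(-0.25, 1.25, by = 0.01)
  grid <- expand.grid(u = cg, v = cg)
  S <- Sgrid(grid$u, grid$v)
  D <- sweep(-2 * (pts %*% t(S)), 2, rowSums(S^2), "+")
  wm <- max.col(-D, ties.method = "first")
  bu <- grid$u[wm]; bv <- grid$v[wm]
  fg <- seq(-0.015, 0.015, by = 1e-3)
  loc <- expand.grid(du = fg, dv = fg)
  for (i in seq_len(n)) {
    uu <- bu[i] + loc$du; vv <- bv[i] + loc$dv
    Sl <- Sgrid(uu, vv)
    d2 <- (Sl[, 1] - pts[i, 1])^2 + (Sl[, 2] - pts[i, 2])^2 +
      (Sl[, 3] - pts[i, 3])^2
    j <- which.min(d2)
    bu[i] <- uu[j]; bv[i] <- vv[j]
  }
  # oracle labels from the grid foot point
  Su <- cbind(k$b[1] + bv * k$d[1], k$b[2] + bv * k$d[2],
              k$b[3] + bv * k$d[3])
  Sv <- cbind(k$c[1] + bu * k$d[1], k$c[2] + bu * k$d[2],
              k$c[3] + bu * k$d[3])
  foot <- cbind(k$a[1] + bu * k$b[1] + bv * k$c[1] + bu * bv * k$d[1],
                k$a[2] + bu * k$b[2] + bv * k$c[2] + bu * bv * k$d[2],
                k$a[3] + bu * k$b[3] + bv * k$c[3] + bu * bv * k$d[3])
  nrm <- cbind(Su[, 2] * Sv[, 3] - Su[, 3] * Sv[, 2],
               Su[, 3] * Sv[, 1] - Su[, 1] * Sv[, 3],
               Su[, 1] * Sv[, 2] - Su[, 2] * Sv[, 1])
  sgn <- sign(nrm %*% fr$x_axis); sgn[sgn == 0] <- 1
  signed <- rowSums((pts - foot) * nrm) * drop(sgn) /
    sqrt(rowSums(nrm^2))
  oval <- ((bu - 0.5) / 0.5)^2 + ((bv - 0.5) / 0.5)^2
  oracle <- ifelse(oval <= 1 & signed < -1e-9, "cochlea", "middle_ear")
  # compare away from the oval rim and the surface itself (the oracle grid
  # quantises (u,v), so only near-boundary points may differ)
  away <- abs(oval - 1) > 0.05 & abs(signed) > 0.02
  expect_gt(sum(away), 700)
  expect_identical(lab[away], oracle[away])
})

test_that("classification is invariant under joint rigid motion", {
  set.seed(23)
  fids <- cochlear_fiducials(c(0, 0, 4), c(0, 0, 0), c(3, 0, 1))
  fr <- fit_ccs(fids)
  patch <- rwm_patch(c(0.2, -1, -1), c(-0.2, 1, -1), c(-0.2, -1, 1),
                     c(0.2, 1, 1))
  pts <- cbind(runif(200, -1, 1), runif(200, -1, 1), runif(200, -1, 1))
  lab <- classify_side(patch, fr, pts)
  R <- random_rotation(); tr <- c(4, -7, 2)
  mv <- function(p) sweep(p %*% t(R), 2, tr, "+")
  fr2 <- fit_ccs(cochlear_fiducials(drop(R %*% fids$apex) + tr,
                                    drop(R %*% fids$basal) + tr,
                                    drop(R %*% fids$rw_center) + tr))
  patch2 <- rwm_patch(mv(rbind(patch$p00))[1, ], mv(rbind(patch$p10))[1, ],
                      mv(rbind(patch$p01))[1, ], mv(rbind(patch$p11))[1, ])
  lab2 <- classify_side(patch2, fr2, mv(pts))
  expect_identical(lab2, lab)
})

test_that("degenerate patches and membrane file round trips behave", {
  fr <- fit_ccs(cochlear_fiducials(c(0, 0, 4), c(0, 0, 0), c(3, 0, 1)))
  expect_error(rwm_patch(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  p <- canonical_saddle()
  f <- withr::local_tempfile(fileext = ".mrk.json")
  write_membrane_points(p, f)
  p2 <- read_membrane_points(f)
  expect_equal(p2$p00, p$p00)
  expect_equal(p2$p11, p$p11)
})
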