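# Volume, membrane contact area, Dice/Jaccard and rule attribution.

test_that("niche volume is voxel count times voxel volume", {
  g <- make_vol(array(0, c(20, 20, 20)), spacing = 0.1)
  m <- array(FALSE, c(20, 20, 20)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(niche_volume(m, g), 1000 * 0.001)
  expect_equal(niche_volume(array(FALSE, c(20, 20, 20)), g), 0)
  aniso <- volume_image(array(0, c(20, 20, 20)), c(0.1, 0.1, 0.2))
  m2 <- array(FALSE, c(20, 20, 20)); m2[seq_len(500)] <- TRUE
  expect_equal(niche_volume(m2, aniso), 500 * 0.1 * 0.1 * 0.2)
  # additive over disjoint masks
  a <- array(FALSE, c(20, 20, 20)); a[1:5, , ] <- TRUE
  b <- array(FALSE, c(20, 20, 20)); b[6:9, , ] <- TRUE
  expect_equal(niche_volume(a | b, g),
               niche_volume(a, g) + niche_volume(b, g))
})

test_that("membrane contact area counts the pit floor exactly", {
  ph <- pit_phantom()
  fr <- fit_ccs(ph$fiducials)
  side <- classify_side(ph$membrane_truth, fr,
                        voxel_centers_world(ph$volume))
  a <- rwm_area(ph$niche_truth, ph$membrane_truth, fr, ph$volume,
                side = side)
  # 10 x 10 floor voxels at 0.1 mm -> 1.0 mm^2
  expect_equal(a, 1.0)
  # a segmentation nowhere near the membrane has zero contact area
  far <- array(FALSE, dim(ph$niche_truth))
  far[1:3, 1:3, 1:3] <- TRUE
  expect_equal(rwm_area(far, ph$membrane_truth, fr, ph$volume,
                        side = side), 0)
})

test_that("contact area scales with the squared spacing", {
  # same voxel topology at doubled spacing quadruples the area
  for (sp in c(0.1, 0.2)) {
    ph <- generate_phantom(phantom_spec(spacing = sp, edge = 30 * sp,
                                       niche_dims = c(10 * sp, 10 * sp,
                                                      5 * sp),
                                       noise_sigma = 0, mouth = "sealed"))
    fr <- fit_ccs(ph$fiducials)
    a <- rwm_area(ph$niche_truth, ph$membrane_truth, fr, ph$volume)
    expect_equal(a, 100 * sp^2)
  }
})

test_that("overlap matches brute-force set computation on random pairs", {
  set.seed(41)
  for (i in 1:100) {
    d <- sample(3:20, 3, replace = TRUE)
    a <- array(runif(prod(d)) < runif(1, 0.05, 0.6), d)
    b <- array(runif(prod(d)) < runif(1, 0.05, 0.6), d)
    if (sum(a) + sum(b) == 0) next
    ov <- overlap(a, b)
    # independent brute-force via linear index set operations
    ia <- which(as.vector(a)); ib <- which(as.vector(b))
    inter <- length(intersect(ia, ib))
    uni <- length(union(ia, ib))
    expect_identical(ov$dsc, 2 * inter / (length(ia) + length(ib)))
    expect_identical(ov$jaccard, inter / uni)
    expect_lt(abs(ov$jaccard - ov$dsc / (2 - ov$dsc)), 1e-12)
    expect_lte(ov$jaccard, ov$dsc + 1e-15)
  }
})

test_that("overlap handles the canonical examples and empty input", {
  a <- array(FALSE, c(10, 10, 10)); a[1:100] <- TRUE
  expect_equal(overlap(a, a), list(dsc = 1, jaccard = 1))
  b <- array(FALSE, c(10, 10, 10)); b[101:200] <- TRUE
  expect_equal(overlap(a, b), list(dsc = 0, jaccard = 0))
  ab <- array(FALSE, c(10, 10, 10)); ab[51:150] <- TRUE
  ov <- overlap(a, ab)
  expect_equal(ov$dsc, 0.5)
  expect_equal(ov$jaccard, 1 / 3)
  e <- array(FALSE, c(10, 10, 10))
  expect_error(overlap(e, e), "undefined")
})

test_that("rule attribution reports exact constructed shares", {
  ph <- pit_phantom()
  fr <- fit_ccs(ph$fiducials)
  vol <- ph$volume
  side <- classify_side(ph$membrane_truth, fr, voxel_centers_world(vol))
  lmax <- sqrt(sum((dim(vol$data) * vol$spacing)^2))
  params <- fill_parameters(c(0.25, 0, 0), 0.4)
  semi <- fill_niche(vol, ph$bone_truth, ph$membrane_truth, fr, params,
                     side)
  # manual = semi-automated mask: all fractions zero
  attr0 <- rule_attribution(semi$mask, ph$bone_truth, ph$membrane_truth,
                            fr, params, vol, semi = semi, side = side)
  expect_equal(unname(attr0$fractions), c(0, 0, 0, 0))
  expect_equal(attr0$residual_vs_semi, 0)
  # manual = truth plus a band beyond the level: step 3 share is exact
  ctrs <- voxel_centers_world(vol)
  dist <- sqrt((ctrs[, 1] - 0.25)^2 + ctrs[, 2]^2 + ctrs[, 3]^2)
  band <- array(dist > 0.4 & dist <= 0.45, dim(vol$data)) &
    ph$niche_truth
  manual <- (ph$niche_truth & array(dist <= 0.4, dim(vol$data))) | band
  att <- rule_attribution(manual, ph$bone_truth, ph$membrane_truth, fr,
                          params, vol, side = side)
  expect_equal(att$fractions[["step3"]], sum(band) / sum(manual))
  expect_equal(att$fractions[["step1"]], 0)
  expect_equal(att$fractions[["step2"]], 0)
  # single-step fractions never exceed the combined fraction
  set.seed(42)
  for (i in 1:20) {
    rnd <- array(runif(prod(dim(vol$data))) < 0.1, dim(vol$data))
    if (!any(rnd)) next
    at <- rule_attribution(rnd, ph$bone_truth, ph$membrane_truth, fr,
                           params, vol, side = side)
    expect_lte(max(at$fractions[1:3]), at$fractions[[4]] + 1e-15)
  }
  expect_error(rule_attribution(array(FALSE, dim(vol$data)),
                                ph$bone_truth, ph$membrane_truth, fr,
                                params, vol), "empty")
})

test_that("overlap_report bundles consistent quantities", {
  ph <- pit_phantom()
  fr <- fit_ccs(ph$fiducials)
  vol <- ph$volume
  side <- classify_side(ph$membrane_truth, fr, voxel_centers_world(vol))
  lmax <- sqrt(sum((dim(vol$data) * vol$spacing)^2))
  params <- fill_parameters(c(0.25, 0, 0), lmax)
  semi <- fill_niche(vol, ph$bone_truth, ph$membrane_truth, fr, params,
                     side)
  manual <- make_oversegmentation(ph, 1, seed = 7)
  rep <- overlap_report(manual, semi, ph$membrane_truth, fr, vol, params,
                        ph$bone_truth, side = side)
  expect_equal(rep$jaccard, rep$dsc / (2 - rep$dsc), tolerance = 1e-13)
  expect_lte(rep$intersection_volume,
             min(rep$volume_a, rep$volume_b) + 1e-12)
  expect_gte(rep$volume_a, rep$volume_b)  # over-segmentation is larger
  f <- withr::local_tempfile(fileext = ".json")
  write_overlap_report(rep, f)
  js <- jsonlite::fromJSON(f)
  expect_equal(js$dsc, rep$dsc, tolerance = 1e-12)
})
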