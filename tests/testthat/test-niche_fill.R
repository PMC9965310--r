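# Crater-lake niche filling, spill level estimation and the three
# exclusion rules.

pit_setup <- function(ph = pit_phantom()) {
  list(ph = ph, fr = fit_ccs(ph$fiducials), vol = ph$volume,
       bone = ph$bone_truth, patch = ph$membrane_truth,
       lmax = sqrt(sum((dim(ph$volume$data) * ph$volume$spacing)^2)))
}

test_that("unlimited-level fill recovers exactly the 500 pit voxels", {
  s <- pit_setup()
  expect_identical(sum(s$ph$niche_truth), 500L)
  seg <- fill_niche(s$vol, s$bone, s$patch, s$fr,
                    fill_parameters(c(0.25, 0, 0), s$lmax))
  expect_identical(seg$mask, s$ph$niche_truth)
  # brute-force oracle: candidate predicate evaluated per voxel
  ctrs <- index_to_world(s$vol, which(array(TRUE, dim(s$vol$data)),
                                      arr.ind = TRUE) - 1)
  inside_pit <- abs(ctrs[, 2]) < 0.5 & abs(ctrs[, 3]) < 0.5 &
    ctrs[, 1] > 0 & ctrs[, 1] < 0.5
  expect_identical(as.vector(seg$mask), inside_pit)
})

test_that("fill provenance and containment invariants hold", {
  s <- pit_setup()
  seg <- fill_niche(s$vol, s$bone, s$patch, s$fr,
                    fill_parameters(c(0.25, 0, 0), s$lmax))
  expect_false(any(seg$mask & s$bone))
  expect_identical(sum(seg$provenance == 0L), sum(seg$mask))
  expect_true(all(seg$provenance[s$bone & seg$provenance != 1L] == 2L))
})

test_that("a half-voxel level keeps at most the seed voxel", {
  s <- pit_setup()
  seg <- fill_niche(s$vol, s$bone, s$patch, s$fr,
                    fill_parameters(c(0.25, 0.02, 0.02), 0.05))
  expect_lte(sum(seg$mask), 1L)
})

test_that("an all-bone region yields an empty-segmentation error", {
  s <- pit_setup()
  allbone <- array(TRUE, dim(s$vol$data))
  expect_error(fill_niche(s$vol, allbone, s$patch, s$fr,
                          fill_parameters(c(0.25, 0, 0), 1)),
               "empty niche.*bone")
})

test_that("fill is monotone in level and in bone threshold", {
  s <- pit_setup()
  side <- classify_side(s$patch, s$fr, voxel_centers_world(s$vol))
  kept_at <- function(L) fill_niche(s$vol, s$bone, s$patch, s$fr,
                                    fill_parameters(c(0.25, 0, 0), L),
                                    side)$mask
  levels <- c(0.2, 0.35, 0.5, 0.8)
  masks <- lapply(levels, kept_at)
  for (i in seq_len(length(levels) - 1))
    expect_true(all(masks[[i]] <= masks[[i + 1]]))
  # shrinking the bone mask (raising the threshold) never shrinks the fill
  smaller_bone <- s$bone
  smaller_bone[, , 1:10] <- FALSE
  seg_small <- fill_niche(s$vol, smaller_bone, s$patch, s$fr,
                          fill_parameters(c(0.25, 0, 0), 0.5), side)
  expect_true(all(masks[[3]] <= seg_small$mask))
})

test_that("spill level on the open pit stays inside the walls", {
  ph <- pit_phantom_flush()
  fr <- fit_ccs(ph$fiducials)
  ctr <- c(0.25, 0, 0)
  side <- classify_side(ph$membrane_truth, fr,
                        voxel_centers_world(ph$volume))
  L <- estimate_spill_level(ph$volume, ph$bone_truth, ph$membrane_truth,
                            fr, ctr, side = side)
  seg <- fill_niche(ph$volume, ph$bone_truth, ph$membrane_truth, fr,
                    fill_parameters(ctr, L), side)
  w <- index_to_world(ph$volume, which(seg$mask, arr.ind = TRUE) - 1)
  expect_lt(max(abs(w[, 2:3])), 0.5)      # inside the pit walls
  # two voxel edges above the spill level the fill reaches a region face
  seg2 <- fill_niche(ph$volume, ph$bone_truth, ph$membrane_truth, fr,
                     fill_parameters(ctr, L + 0.2), side)
  d <- dim(seg2$mask)
  face <- array(FALSE, d)
  face[c(1, d[1]), , ] <- TRUE; face[, c(1, d[2]), ] <- TRUE
  face[, , c(1, d[3])] <- TRUE
  expect_true(any(seg2$mask & face))
  # the level is insensitive to the pit's truth depth (rim unchanged)
  ph2 <- generate_phantom(phantom_spec(spacing = 0.1,
                                      niche_dims = c(1, 1, 0.7),
                                      noise_sigma = 0, mouth = "flush"))
  L2 <- estimate_spill_level(ph2$volume, ph2$bone_truth,
                             ph2$membrane_truth, fit_ccs(ph2$fiducials),
                             ctr)
  expect_lt(abs(L2 - L), 0.025 + 1e-9)
})

test_that("a sealed cavity reports the region diagonal as spill level", {
  s <- pit_setup()
  L <- estimate_spill_level(s$vol, s$bone, s$patch, s$fr, c(0.25, 0, 0))
  expect_equal(L, s$lmax)
})

test_that("apply_niche_rules decomposes removals per rule", {
  s <- pit_setup()
  side <- classify_side(s$patch, s$fr, voxel_centers_world(s$vol))
  params <- fill_parameters(c(0.25, 0, 0), 0.6)
  seg <- fill_niche(s$vol, s$bone, s$patch, s$fr, params, side)
  # self-application removes nothing
  rules <- apply_niche_rules(seg$mask, s$bone, s$patch, s$fr, params,
                             s$vol, side)
  expect_identical(unname(rules$removed), c(0L, 0L, 0L, 0L))
  # dilated truth: removals match the per-voxel predicates
  dil <- seg$mask
  for (i in 1:2) dil <- rwniche:::dilate26(dil)
  rules2 <- apply_niche_rules(dil, s$bone, s$patch, s$fr, params, s$vol,
                              side)
  d <- dim(dil)
  coch <- array(side == "cochlea", d)
  ctrs <- voxel_centers_world(s$vol)
  above <- array(sqrt((ctrs[, 1] - 0.25)^2 + ctrs[, 2]^2 + ctrs[, 3]^2) >
                   0.6, d)
  expect_identical(rules2$step1, dil & !coch)
  expect_identical(rules2$step2, dil & !s$bone)
  expect_identical(rules2$step3, dil & !above)
  expect_identical(rules2$all, dil & !coch & !s$bone & !above)
  expect_equal(unname(rules2$removed),
               c(sum(dil & coch), sum(dil & s$bone), sum(dil & above),
                 sum(dil) - sum(rules2$all)))
  # combined survivors are a subset of each single-step survivor set
  expect_true(all(rules2$all <= rules2$step1))
  expect_true(all(rules2$all <= rules2$step2))
  expect_true(all(rules2$all <= rules2$step3))
  # empty input
  rules3 <- apply_niche_rules(array(FALSE, d), s$bone, s$patch, s$fr,
                              params, s$vol, side)
  expect_identical(unname(rules3$removed), c(0L, 0L, 0L, 0L))
  expect_false(any(rules3$all))
})

test_that("provenance label maps round trip through NRRD", {
  s <- pit_setup()
  seg <- fill_niche(s$vol, s$bone, s$patch, s$fr,
                    fill_parameters(c(0.25, 0, 0), s$lmax))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_provenance_nrrd(seg, f)
  lab <- read_nrrd(f)
  expect_identical(array(as.integer(lab$data), dim(lab$data)),
                   array(as.integer(seg$provenance), dim(seg$provenance)))
})
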