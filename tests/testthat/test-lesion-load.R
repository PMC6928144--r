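test_that("slice profiles count per-slice areas and their maximum", {
  tr <- tube_tract(c(10, 5, 2))
  prof <- slice_profile(tr)
  expect_identical(prof$m, c(10L, 5L, 2L))
  expect_identical(prof$m_star, 10L)
  expect_identical(prof$z_support, 1:3)

  single <- tube_tract(c(0, 7, 0))
  expect_identical(slice_profile(single)$m_star, 7L)

  expect_error(slice_profile(mask_vol(array(0L, c(3, 3, 3)))),
               class = "cstload_empty_tract_error")
})

test_that("weighted lesion load matches the hand-computed slice weighting", {
  # tract slice areas [10, 5, 2]; lesion-in-tract counts [0, 2, 1]
  # wLL = 2*(10/5) + 1*(10/2) = 9
  tr <- tube_tract(c(10, 5, 2))
  le <- array(0L, c(6, 6, 3))
  le[36 + 1:2] <- 1L   # 2 voxels inside the 5-voxel slice
  le[72 + 1] <- 1L     # 1 voxel inside the 2-voxel slice
  rec <- weighted_lesion_load(mask_vol(le), tr)
  expect_equal(rec$weighted_ll, 9)
  expect_identical(rec$raw_overlap, 3L)
  expect_identical(rec$n_by_slice, c(0L, 2L, 1L))
  expect_equal(rec$weighted_ll, wll_bruteforce(mask_vol(le), tr))

  # empty lesion
  rec0 <- weighted_lesion_load(mask_vol(array(0L, c(6, 6, 3))), tr)
  expect_identical(rec0$raw_overlap, 0L)
  expect_identical(rec0$weighted_ll, 0)

  # constant-area tube: every weight is 1, load = overlap count
  tube <- tube_tract(rep(8, 4), dim = c(6, 6, 4))
  les <- array(0L, c(6, 6, 4)); les[1:5] <- 1L; les[36 + 1:3] <- 1L
  expect_equal(weighted_lesion_load(mask_vol(les), tube)$weighted_ll, 8)

  # grid mismatch
  expect_error(
    weighted_lesion_load(rand_mask(c(6, 6, 3), affine = diag(4) * 2), tr),
    class = "cstload_grid_error")
})

test_that("weighted load equals the per-voxel brute force on random masks", {
  set.seed(101)
  for (i in 1:25) {
    dims <- c(sample(4:9, 1), sample(4:9, 1), sample(3:8, 1))
    tract <- rand_mask(dims, p = runif(1, 0.1, 0.5))
    if (sum(tract$data) == 0) next
    lesion <- rand_mask(dims, p = runif(1, 0.05, 0.5))
    rec <- weighted_lesion_load(lesion, tract)
    oracle <- wll_bruteforce(lesion, tract)
    expect_equal(rec$weighted_ll, oracle, tolerance = 1e-9)
    expect_gte(rec$weighted_ll, rec$raw_overlap)
  }
})

test_that("weighted load is translation-invariant and additive over disjoint lesions", {
  set.seed(33)
  tract_core <- tube_tract(c(12, 8, 4, 2), dim = c(6, 5, 4))$data
  lesion_core <- array((runif(6 * 5 * 4) < 0.25) * 1L, c(6, 5, 4))
  embed <- function(core, at) {
    out <- array(0L, c(9, 9, 7))
    out[at[1]:(at[1] + 5), at[2]:(at[2] + 4), at[3]:(at[3] + 3)] <- core
    mask_vol(out)
  }
  base <- weighted_lesion_load(embed(lesion_core, c(1, 1, 1)),
                               embed(tract_core, c(1, 1, 1)))$weighted_ll
  shifted <- weighted_lesion_load(embed(lesion_core, c(3, 2, 4)),
                                  embed(tract_core, c(3, 2, 4)))$weighted_ll
  expect_equal(shifted, base, tolerance = 1e-12)
  lesion <- embed(lesion_core, c(1, 1, 1))
  tract <- embed(tract_core, c(1, 1, 1))

  # additivity: split the lesion voxelwise into two disjoint parts
  idx <- which(lesion$data == 1L)
  a <- array(0L, dim(lesion$data)); b <- array(0L, dim(lesion$data))
  a[idx[seq_along(idx) %% 2 == 0]] <- 1L
  b[idx[seq_along(idx) %% 2 == 1]] <- 1L
  expect_equal(weighted_lesion_load(mask_vol(a), tract)$weighted_ll +
                 weighted_lesion_load(mask_vol(b), tract)$weighted_ll,
               base, tolerance = 1e-12)
})

test_that("weighted equals raw exactly when all overlapped slices are maximal", {
  tract <- tube_tract(c(10, 10, 4))
  le <- array(0L, c(6, 6, 3)); le[1:3] <- 1L  # only the first (maximal) slice
  rec <- weighted_lesion_load(mask_vol(le), tract)
  expect_identical(rec$weighted_ll, as.numeric(rec$raw_overlap))
  le[72 + 1] <- 1L  # now also the 4-voxel slice: strict inequality
  rec2 <- weighted_lesion_load(mask_vol(le), tract)
  expect_gt(rec2$weighted_ll, rec2$raw_overlap)
})

test_that("lesion load tables cover subject x tract with the hemisphere policy", {
  atlas <- make_tract_template(default_tract_specs())
  lesions <- list(
    s1 = make_lesion(c(42, 31, 14), c(4, 4, 5), dim = atlas$dim,
                     affine = atlas$affine),
    s2 = make_lesion(c(22, 33, 20), c(5, 4, 4), dim = atlas$dim,
                     affine = atlas$affine))
  tbl <- lesion_load_table(lesions, atlas, hemisphere = c("R", "L"))
  expect_identical(nrow(tbl), 14L)
  expect_setequal(unique(tbl$tract), c("SMATT", smatt_labels()))
  # union raw overlap dominates any sub-tract raw overlap
  for (id in names(lesions)) {
    sub <- tbl[tbl$subject_id == id, ]
    expect_true(all(sub$raw_overlap[sub$tract == "SMATT"] >=
                      sub$raw_overlap[sub$tract != "SMATT"]))
  }

  # lesion outside every tract scores zero everywhere
  far <- list(far = make_lesion(c(5, 60, 38), c(2, 2, 1),
                                dim = atlas$dim, affine = atlas$affine))
  z <- lesion_load_table(far, atlas, hemisphere = "R")
  expect_true(all(z$weighted_ll == 0))

  expect_error(lesion_load_table(lesions, atlas),
               class = "cstload_policy_error")
  expect_error(lesion_load_table(lesions, atlas, hemisphere = "Q"),
               class = "cstload_policy_error")
})

test_that("flip policy scores mirrored lesions on the canonical hemisphere", {
  atlas <- make_tract_template(default_tract_specs())
  les_L <- make_lesion(c(65 - 42, 31, 14), c(4, 4, 4),
                       dim = atlas$dim, affine = atlas$affine)
  flipped <- lesion_load_table(list(s = les_L), atlas, policy = "flip",
                               canonical_hemisphere = "R")
  manual <- lesion_load_table(list(s = flip_lr(les_L)), atlas,
                              hemisphere = "R")
  expect_equal(flipped$weighted_ll, manual$weighted_ll)
  expect_gt(sum(flipped$weighted_ll), 0)
})

test_that("overlay maps sum lesions voxelwise", {
  a <- rand_mask(c(6, 6, 4), p = 0.3)
  expect_identical(lesion_overlay_map(list(a))$data, a$data)

  d1 <- array(0L, c(6, 6, 4)); d1[1] <- 1L
  d2 <- array(0L, c(6, 6, 4)); d2[100] <- 1L
  ov <- lesion_overlay_map(list(mask_vol(d1), mask_vol(d2)))
  expect_identical(max(ov$data), 1L)

  ov5 <- lesion_overlay_map(rep(list(a), 5))
  expect_identical(max(ov5$data), 5L * max(a$data))

  expect_error(lesion_overlay_map(list(a, rand_mask(c(6, 6, 5)))),
               class = "cstload_grid_error")
})
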