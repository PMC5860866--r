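test_that("sphere offsets reproduce the radius-inclusive voxel counts", {
  expect_equal(nrow(sphere_offsets(0)), 1)
  expect_equal(nrow(sphere_offsets(1)), 7)
  expect_equal(nrow(sphere_offsets(3)), 123)
  expect_error(sphere_offsets(-1), ">= 0")

  # invariant under axis permutation and reflection
  o <- sphere_offsets(2.5)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(o[, c(2, 3, 1)]), key(o))
  expect_identical(key(-o), key(o))
  # deterministic lexicographic order
  expect_identical(o, o[order(o[, 1], o[, 2], o[, 3]), ])
})

test_that("TFCE matches the single-voxel closed form and is monotone", {
  z <- array(0, c(4, 4, 4))
  expect_equal(tfce_transform(z), z)

  z[2, 2, 2] <- 1.37
  tf <- tfce_transform(z, E = 0.5, H = 2, dh = 0.1)
  hs <- seq(0.1, 1.3, by = 0.1)
  expect_equal(tf[2, 2, 2], sum(1^0.5 * hs^2 * 0.1), tolerance = 1e-12)
  expect_equal(sum(tf != 0), 1)

  # negative values are enhanced symmetrically
  expect_equal(tfce_transform(-z), -tf)

  # doubling the map never decreases any TFCE value
  set.seed(90)
  m <- array(rnorm(6^3), c(6, 6, 6))
  t1 <- tfce_transform(m)
  t2 <- tfce_transform(2 * m)
  expect_true(all(abs(t2) >= abs(t1) - 1e-12))

  # cluster extent increases TFCE at fixed height
  a <- array(0, c(8, 4, 4)); a[2, 2, 2] <- 1
  b <- a; b[3, 2, 2] <- 1; b[4, 2, 2] <- 1
  expect_gt(tfce_transform(b)[2, 2, 2], tfce_transform(a)[2, 2, 2])

  # NA voxels are outside the mask and are passed through untouched
  na_map <- array(NA_real_, c(4, 4, 4))
  na_map[2, 2, 2] <- 1.37
  tf_na <- tfce_transform(na_map)
  expect_equal(tf_na[2, 2, 2], tf[2, 2, 2])
  expect_true(all(is.na(tf_na)[-which(!is.na(na_map))]))

  expect_error(tfce_transform(z, dh = 0), "positive")
})

test_that("single-center searchlight equals the ROI pipeline (compositionality)", {
  set.seed(91)
  ms <- gen_model_rdms(6, 3, 0, 30, rng_seed = 92)
  dims <- c(3, 3, 3)
  region <- array(TRUE, dims)
  gv <- gen_searchlight_volume(dims, region, ms[[1]], n_runs = 3,
                               signal_scale = 1, noise_sd = 0.8,
                               rng_seed = 93)
  mv <- lapply(ms, rdm_vectorize)

  # mask with a single center: radius covers the whole volume
  sl <- run_searchlight(gv$data, mv, radius = 5, min_voxels = 2)
  center <- c(2, 2, 2)
  got <- sapply(1:3, function(k) sl[[k]][center[1], center[2], center[3]])

  pd <- pattern_dataset(gv$data$betas, labels = gv$data$labels)
  v <- rdm_vectorize(crossnobis_rdm(pd, noise_model_identity(27)))
  want <- sapply(1:3, function(k) partial_correlation(v, mv[[k]], mv[-k]))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("searchlight recovers a planted representational region", {
  set.seed(94)
  ms <- gen_model_rdms(8, 3, 0, 30, rng_seed = 95)
  mv <- lapply(ms, rdm_vectorize)
  dims <- c(7, 7, 7)
  region <- array(FALSE, dims); region[3:5, 3:5, 3:5] <- TRUE

  inside <- matrix(NA, 5, 3); outside <- matrix(NA, 5, 3)
  for (s in 1:5) {
    gv <- gen_searchlight_volume(dims, region, ms[[1]], n_runs = 4,
                                 signal_scale = 1.5, noise_sd = 1,
                                 rng_seed = 200 + s)
    sl <- run_searchlight(gv$data, mv, radius = 1, min_voxels = 2)
    for (k in 1:3) {
      inside[s, k] <- mean(sl[[k]][gv$truth], na.rm = TRUE)
      outside[s, k] <- mean(sl[[k]][!gv$truth], na.rm = TRUE)
    }
  }
  # the planted model shows strong positive partial r inside the region
  expect_gt(mean(inside[, 1]), 2 * sd(inside[, 1]) / sqrt(5))
  expect_gt(mean(inside[, 1]), 0.1)
  # and roughly nothing outside, for any model
  expect_lt(max(abs(colMeans(outside))), 0.05)
  # the non-planted models do not light up inside either
  expect_lt(max(abs(colMeans(inside)[2:3])), 0.05)
})

test_that("planted-region recovery AUC is high when spheres preserve the geometry", {
  # radius-2 spheres hold 33 voxels, well above the rank (7) of the
  # planted 8-category structure, so each sphere sees the full geometry
  ms <- gen_model_rdms(8, 3, 0, 30, rng_seed = 95)
  mv <- lapply(ms, rdm_vectorize)
  dims <- c(10, 10, 10)
  region <- array(FALSE, dims); region[3:8, 3:8, 3:8] <- TRUE
  auc_of <- function(score, truth) {
    pos <- score[truth & !is.na(score)]
    neg <- score[!truth & !is.na(score)]
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }
  aucs <- sapply(1:5, function(s) {
    gv <- gen_searchlight_volume(dims, region, ms[[1]], n_runs = 4,
                                 signal_scale = 3, noise_sd = 1,
                                 rng_seed = 900 + s)
    sl <- run_searchlight(gv$data, mv, radius = 2)
    auc_of(sl[[1]], gv$truth)
  })
  expect_gt(mean(aucs), 0.9)
})

test_that("an all-noise volume yields null partial-correlation maps", {
  ms <- gen_model_rdms(8, 3, 0, 30, rng_seed = 96)
  mv <- lapply(ms, rdm_vectorize)
  dims <- c(6, 6, 6)
  region <- array(FALSE, dims); region[1, 1, 1] <- TRUE
  gv <- gen_searchlight_volume(dims, region, ms[[1]], n_runs = 4,
                               signal_scale = 0, noise_sd = 1, rng_seed = 97)
  expect_false(any(gv$truth))
  sl <- run_searchlight(gv$data, mv, radius = 1)
  # sphere estimates are spatially correlated, so the map mean has an
  # effective n well below the voxel count; 0.1 is ~3 SE here
  for (k in 1:3) expect_lt(abs(mean(sl[[k]], na.rm = TRUE)), 0.1)
})

test_that("group sign permutation finds a strong planted signal and respects symmetry", {
  set.seed(98)
  dims <- c(6, 6, 6)
  blob <- array(0, dims); blob[2:3, 2:3, 2:3] <- 0.6
  maps <- lapply(1:10, function(i) blob + array(rnorm(prod(dims), sd = 0.2), dims))
  res <- group_sign_permutation(maps, n_perm = 500, rng_seed = 99)
  expect_true(all(res$significant[2:3, 2:3, 2:3]))
  expect_lt(max(res$p_corrected[blob > 0]), 0.05)
  # voxels far from the blob stay unflagged
  expect_false(any(res$significant[5:6, 5:6, 5:6]))

  # flipping every participant's map negates the observed z map but leaves
  # the sign-flip null distribution unchanged
  res_neg <- group_sign_permutation(lapply(maps, function(m) -m),
                                    n_perm = 500, rng_seed = 99)
  expect_equal(res_neg$z, -res$z, tolerance = 1e-10)
  expect_equal(sort(res_neg$max_null), sort(res$max_null), tolerance = 1e-10)

  expect_error(group_sign_permutation(maps[1:3], n_perm = 10), "5 participants")
})
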