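full_mask <- function(dims, voxel = c(1, 1, 1))
  ganglion_mask(array(TRUE, dim = dims), voxel)

test_that("background estimation recovers a constant offset", {
  v <- array(50, dim = c(6, 10, 10))
  v[3, 4:6, 4:6] <- 500
  st <- mito_stack(v, c(1, 1, 1))
  res <- correct_background(st)
  expect_equal(res$background, 50)
  expect_equal(sum(res$stack$voxels == 0), sum(v == 50))

  zero <- mito_stack(array(0, dim = c(4, 6, 6)), c(1, 1, 1))
  expect_identical(correct_background(zero)$stack$voxels, zero$voxels)
  expect_error(correct_background(mito_stack(array(7, dim = c(4, 6, 6)),
                                             c(1, 1, 1))), "background")
})

test_that("simulated background level is estimated within 5%", {
  sim <- simulate_mito_stack(small_mito_params(background_level = 120))
  res <- correct_background(sim$stack, sim$mask)
  expect_lt(abs(res$background - 120) / 120, 0.05)
})

test_that("bleach correction restores frame means, first frame brightest", {
  base <- array(runif(6 * 8 * 8, 10, 100), dim = c(6, 8, 8))
  nt <- 12
  v <- array(0, dim = c(nt, 6, 8, 8))
  for (t in seq_len(nt)) v[t, , , ] <- base * 0.99^(t - 1)
  st <- mito_stack(v, c(1, 1, 1), frame_interval_s = 1)
  res <- correct_bleach(st)
  means <- vapply(seq_len(nt), function(t) mean(res$stack$voxels[t, , , ]), 1)
  expect_true(all(abs(means - means[1]) / means[1] < 0.001))
  expect_true(all(diff(res$factors) >= 0))
  expect_true(all(res$factors >= 1))

  flat <- array(0, dim = c(3, 6, 8, 8))
  for (t in 1:3) flat[t, , , ] <- base
  flat <- mito_stack(flat, c(1, 1, 1), frame_interval_s = 1)
  expect_equal(correct_bleach(flat)$factors, rep(1, 3))
})

test_that("bleach correction preserves genuine spot fluctuation", {
  sim <- simulate_mito_stack(small_mito_params(bleach_rate_per_frame = 0.03,
                                               fluctuation_cv_pct = 12,
                                               n_mito = 40, min_separation_um = 2,
                                               shape_vox = c(10, 16, 128, 128)))
  st <- correct_background(sim$stack, sim$mask)$stack
  st <- correct_bleach(st)$stack
  spots <- detect_spots(stack_frame_for_test(st, 1), sim$mask,
                        min_distance_um = 1.2)
  fl <- track_and_fluctuate(st, spots, sim$mask)
  truth <- sim$truth
  ## correlate against the fluctuation component of the truth (the analysis
  ## chain removes bleach, so the reference must not contain it)
  truth_fl <- sweep(truth$frame_intensity, 1, 0.97^(0:9), `/`)
  cors <- vapply(unique(fl$series$spot_id), function(sid) {
    s <- fl$series[fl$series$spot_id == sid, ]
    sp <- spots[spots$id == sid, ]
    d2 <- (truth$mito$z_um - sp$z_um)^2 + (truth$mito$y_um - sp$y_um)^2 +
      (truth$mito$x_um - sp$x_um)^2
    stats::cor(s$intensity, truth_fl[, which.min(d2)])
  }, 1)
  expect_gt(mean(cors), 0.9)
})

test_that("volume detection arithmetic and trivial bounds", {
  mask <- full_mask(c(10, 10, 10))
  fr <- array(0, dim = c(10, 10, 10))
  fr[1:2, 1:10, 1:5] <- 80  # 100 voxels
  res <- detect_volume(fr, mask, threshold = 50)
  expect_equal(res$volume_ratio, 0.1)
  expect_equal(res$total_mito_volume_um3, 100)
  none <- detect_volume(fr, mask, threshold = 1e6)
  expect_equal(none$volume_ratio, 0)
  expect_equal(none$total_mito_volume_um3, 0)
})

test_that("two point sources 5 um apart are resolved as two spots", {
  dims <- c(16, 64, 64); voxel <- c(0.5, 0.25, 0.25)
  fr <- array(0, dim = dims)
  fr[8, 32, 32] <- 5000   # (3.75, 7.875, 7.875) um voxel centre
  fr[8, 32, 52] <- 5000   # 5 um away along x
  mask <- full_mask(dims, voxel)
  sp <- detect_spots(fr, mask, min_distance_um = 2, intensity_floor = 100)
  expect_equal(nrow(sp), 2)
  truth <- rbind(c(3.75, 7.875, 7.875), c(3.75, 7.875, 12.875))
  got <- as.matrix(sp[order(sp$x_um), c("z_um", "y_um", "x_um")])
  expect_lt(max(abs(got - truth)), 0.5)
  uniform <- array(10, dim = dims)
  expect_equal(nrow(detect_spots(uniform, mask, intensity_floor = 1)), 0)
})

test_that("density is spots per 1000 cubic micron of mask", {
  mask <- full_mask(c(10, 10, 30))  # 3000 um^3
  spots <- data.frame(id = 1:12, z_um = 1, y_um = 1, x_um = 1,
                      centre_intensity = 1, log_response = 1)
  expect_equal(density_per_1000um3(spots, mask), 4)
  expect_equal(density_per_1000um3(spots[0, ], mask), 0)
})

test_that("single-mitochondrion volumes from connected components", {
  vox <- c(0.5, 0.5, 0.5)
  fr <- array(0, dim = c(6, 6, 6))
  fr[2:3, 2:3, 2:3] <- 100            # one 8-voxel cube = 1 um^3
  mask <- full_mask(c(6, 6, 6), vox)
  res <- single_mito_volumes(fr, mask, threshold = 50)
  expect_equal(res$mean_single_volume_um3, 1)
  expect_equal(res$n_components, 1L)

  fr2 <- array(0, dim = c(8, 8, 8))
  fr2[2:3, 2:3, 2:3] <- 100
  fr2[6:7, 6:7, 6:7] <- 100
  res2 <- single_mito_volumes(fr2, full_mask(c(8, 8, 8), vox), threshold = 50)
  expect_equal(res2$n_components, 2L)
  expect_equal(res2$mean_single_volume_um3, 1)
  expect_error(single_mito_volumes(fr2, full_mask(c(8, 8, 8), vox),
                                   threshold = 1000), "supra-threshold")
})

test_that("a bridged double blob is split by its two seeds", {
  vox <- c(0.5, 0.5, 0.5)
  fr <- array(0, dim = c(5, 5, 11))
  fr[2:4, 2:4, 2:4] <- 100
  fr[2:4, 2:4, 8:10] <- 100
  fr[3, 3, 5:7] <- 60                  # dim bridge connects the cores
  mask <- full_mask(c(5, 5, 11), vox)
  whole <- single_mito_volumes(fr, mask, threshold = 50)
  expect_equal(whole$n_components, 1L)
  seeds <- data.frame(id = 1:2,
                      z_um = c(1.25, 1.25), y_um = c(1.25, 1.25),
                      x_um = c(1.25, 4.25),
                      centre_intensity = c(100, 100), log_response = c(1, 1))
  split <- single_mito_volumes(fr, mask, threshold = 50, spots = seeds)
  expect_equal(split$n_components, 2L)
  expect_equal(sum(split$volumes_um3), sum(whole$volumes_um3))
})

test_that("top-spot selection matches a full-sort oracle with ties", {
  sp <- data.frame(id = 1:3, z_um = c(1, 2, 3), y_um = 0, x_um = 0,
                   centre_intensity = c(5, 9, 7), log_response = 0)
  expect_equal(select_top_spots(sp, 500)$id, c(2, 3, 1))
  expect_equal(select_top_spots(sp, 2)$centre_intensity, c(9, 7))
  set.seed(3)
  big <- data.frame(id = 1:200, z_um = runif(200), y_um = runif(200),
                    x_um = runif(200),
                    centre_intensity = sample(1:40, 200, TRUE),
                    log_response = 0)
  oracle <- big[order(-big$centre_intensity, big$z_um, big$y_um, big$x_um), ]
  for (n in c(1, 37, 200, 500)) {
    got <- select_top_spots(big, n)
    expect_identical(got$id, oracle$id[seq_len(min(n, 200))])
  }
})

test_that("fluctuation scoring: constant spot scores 0, sinusoid matches closed form", {
  dims <- c(8, 16, 16); vox <- c(0.5, 0.25, 0.25); nt <- 32
  v <- array(0, dim = c(nt, dims))
  amp <- 0.1
  for (t in seq_len(nt)) {
    v[t, 4:5, 8:9, 8:9] <- 100 * (1 + amp * sin(2 * pi * (t - 1) / 8))
    v[t, 2, 3, 3] <- 100
  }
  st <- mito_stack(v, vox, frame_interval_s = 1)
  spots <- data.frame(id = 1:2,
                      z_um = c(2.25, 0.75), y_um = c(2.125, 0.625),
                      x_um = c(2.125, 0.625),
                      centre_intensity = c(100, 100), log_response = c(1, 1))
  fl <- track_and_fluctuate(st, spots, full_mask(dims, vox),
                            sample_radius_um = 0.3)
  s1 <- fl$scores$fluctuation_score_pct[fl$scores$spot_id == 1]
  s2 <- fl$scores$fluctuation_score_pct[fl$scores$spot_id == 2]
  closed <- 100 * amp / sqrt(2) * sqrt(nt / (nt - 1))  # sample-SD convention
  expect_equal(s1, closed, tolerance = 1e-9)
  expect_equal(s2, 0)
  expect_true(all(abs(tapply(fl$series$variation_pct, fl$series$spot_id, mean))
                  < 1e-6))
})

test_that("dilution factors reproduce the printed injection arithmetic", {
  expect_equal(dilution_factor(150, 6, "nl", "mm3"), 40)
  expect_equal(dilution_factor(150, 500, "nl", "ul"), 10000 / 3)
  expect_equal(dilution_factor(5, 5, "ul", "ul"), 1)
  expect_error(dilution_factor(0, 5), "positive")
})

test_that("volume ratio and density are invariant under joint intensity scaling", {
  sim <- simulate_mito_stack(small_mito_params(shape_vox = c(1, 16, 96, 96)))
  fr <- correct_background(sim$stack, sim$mask)$stack$voxels
  mask <- sim$mask
  thr <- default_threshold(fr, mask)
  a <- detect_volume(fr, mask, thr)
  b <- detect_volume(fr * 11, mask, thr * 11)
  expect_equal(a$volume_ratio, b$volume_ratio)
  sa <- detect_spots(fr, mask, intensity_floor = 0.4 * thr)
  sb <- detect_spots(fr * 11, mask, intensity_floor = 0.4 * thr * 11)
  expect_equal(density_per_1000um3(sa, mask), density_per_1000um3(sb, mask))
})
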