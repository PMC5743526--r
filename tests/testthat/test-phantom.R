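test_that("phantom spec validates geometry and acquisition parameters", {
  spec <- phantom_spec()
  expect_s3_class(spec, "phantom_spec")
  expect_equal(nrow(spec$veins), 36L)
  expect_equal(nrow(spec$nuclei), 4L)
  # every (diameter, susceptibility) pair at all four angles
  cells <- table(spec$veins$diam, spec$veins$chi)
  expect_true(all(cells == 4L))
  # the 0.2-ppm nucleus is the largest
  expect_equal(spec$nuclei$chi[which.max(spec$nuclei$r)], 0.2)
  full <- phantom_spec(full = TRUE)
  expect_equal(full$n, c(800L, 640L, 640L))
  expect_error(phantom_spec(vein_len = 40), "outside the brain")
  expect_error(phantom_spec(shrink = 3), "divide")
  expect_error(phantom_spec(snr = -1), "positive")
})

test_that("rasterization assigns primitives by point-in-shape tests", {
  spec <- phantom_spec(n = c(64, 64, 64))
  # no primitives -> susceptibility identically zero, magnitude = brain
  empty <- spec
  empty$nuclei <- spec$nuclei[0, ]
  empty$veins <- spec$veins[0, ]
  ras0 <- rasterize_phantom(empty)
  expect_equal(max(abs(vol_data(ras0$chi))), 0)
  expect_equal(sort(unique(as.vector(vol_data(ras0$magnitude)))), c(0, 1))
  # a single sphere: interior at its value, exterior untouched
  one <- empty
  one$nuclei <- spec$nuclei[4, ] # chi = 0.2
  ras1 <- rasterize_phantom(one)
  chi <- vol_data(ras1$chi)
  expect_equal(sort(unique(as.vector(chi))), c(0, 0.2))
  expect_equal(sum(chi == 0.2) * spec$voxel_size[1]^3,
               4 / 3 * pi * one$nuclei$r^3, tolerance = 0.15)
  expect_equal(unique(vol_data(ras1$magnitude)[chi == 0.2]), 0.7)
})

test_that("sub-voxel veins rasterize to 1-4 voxels per cross-section", {
  spec <- phantom_spec(n = c(64, 64, 64))
  one <- spec
  one$nuclei <- spec$nuclei[0, ]
  vz <- spec$veins[spec$veins$diam == 0.25 & spec$veins$theta == 0, ][1, ]
  one$veins <- vz
  chi <- vol_data(rasterize_phantom(one)$chi)
  v <- spec$voxel_size[3]
  iz <- which((seq_len(64) - 0.5) * v > vz$z - vz$len / 2 + v &
                (seq_len(64) - 0.5) * v < vz$z + vz$len / 2 - v)
  counts <- vapply(iz, function(z) sum(chi[, , z] > 0), integer(1))
  expect_true(all(counts >= 1 & counts <= 4))
})

test_that("simulated phase follows the gyromagnetic scaling and is linear in TE", {
  # 1 ppm at 3 T, TE = 20 ms -> 2*pi*42.576e6*3*1e-6*0.02 radians
  expect_equal(phase_scaling(3, 0.02), 2 * pi * 42.576e6 * 3 * 0.02 * 1e-6,
               tolerance = 1e-12) # = 16.0508 rad per ppm
  spec <- phantom_spec(n = c(32, 32, 32), voxel_size = 1)
  spec$nuclei <- spec$nuclei[0, ]
  spec$veins <- spec$veins[0, ]
  chi <- rasterize_phantom(spec)$chi
  expect_equal(max(abs(vol_data(simulate_phase(chi, 3, 0.02)))), 0)
  chi$data[16, 16, 16] <- 0.3
  p1 <- simulate_phase(chi, 3, 0.02)
  p2 <- simulate_phase(chi, 3, 0.04)
  expect_equal(vol_data(p2), 2 * vol_data(p1), tolerance = 1e-12)
})

test_that("Fourier-crop shrinking halves the grid and preserves DC exactly", {
  m <- vol3d(array(0.8, c(16, 16, 16)), 0.25)
  p <- vol3d(array(0.3, c(16, 16, 16)), 0.25)
  out <- shrink_complex(m, p, 2)
  expect_equal(dim(vol_data(out$magnitude)), c(8L, 8L, 8L))
  expect_equal(out$magnitude$voxel_size, rep(0.5, 3))
  # uniform complex image passes through unchanged
  expect_equal(vol_data(out$magnitude), array(0.8, c(8, 8, 8)),
               tolerance = 1e-12)
  expect_equal(vol_data(out$phase), array(0.3, c(8, 8, 8)),
               tolerance = 1e-12)
  # factor 1 is the identity
  idn <- shrink_complex(m, p, 1)
  expect_identical(vol_data(idn$magnitude), vol_data(m))
  expect_error(shrink_complex(m, p, 3), "divide")
  # general DC preservation
  set.seed(1)
  mr <- vol3d(array(runif(16^3, 0.5, 1), c(16, 16, 16)))
  pr <- vol3d(array(runif(16^3, -0.5, 0.5), c(16, 16, 16)))
  sc <- shrink_complex(mr, pr, 2)
  cc_big <- mean(vol_data(mr) * exp(1i * vol_data(pr)))
  cc_small <- mean(vol_data(sc$magnitude) * exp(1i * vol_data(sc$phase)))
  expect_equal(cc_small, cc_big, tolerance = 1e-12)
})

test_that("complex noise hits the target SNR and is seed-reproducible", {
  n <- 48
  m <- vol3d(array(1, c(n, n, n)))
  p <- vol3d(array(0, c(n, n, n)))
  bm <- array(1, c(n, n, n))
  a <- add_noise(m, p, snr = 30, seed = 11, brain_mask = bm)
  b <- add_noise(m, p, snr = 30, seed = 11, brain_mask = bm)
  expect_identical(vol_data(a$magnitude), vol_data(b$magnitude))
  expect_identical(vol_data(a$phase), vol_data(b$phase))
  # real-channel SD over >= 1e4 voxels matches mean(brain)/snr
  re <- vol_data(a$magnitude) * cos(vol_data(a$phase))
  expect_equal(sd(re - 1), 1 / 30, tolerance = 0.03)
  inf <- add_noise(m, p, snr = Inf, seed = 1, brain_mask = bm)
  expect_identical(vol_data(inf$magnitude), vol_data(m))
})

test_that("block-average reference preserves partial volumes and totals", {
  a <- array(0, c(8, 8, 8))
  a[1, 1, 1] <- 0.2
  ref <- make_reference(vol3d(a, 0.25), 2)
  expect_equal(vol_data(ref)[1, 1, 1], 0.2 / 8)
  expect_equal(ref$voxel_size, rep(0.5, 3))
  set.seed(2)
  b <- array(rnorm(16^3), c(16, 16, 16))
  rb <- make_reference(vol3d(b), 2)
  expect_equal(sum(vol_data(rb)) * 8, sum(b), tolerance = 1e-10)
  expect_equal(vol_data(make_reference(vol3d(array(0.1, c(8, 8, 8))), 2)),
               array(0.1, c(4, 4, 4)))
})

test_that("ROI set covers veins, nuclei, brain and artifact patches", {
  spec <- phantom_spec()
  ras <- rasterize_phantom(spec)
  ref <- make_reference(ras$chi, spec$shrink)
  rois <- make_rois(ref, spec)
  expect_length(rois$vein, 9L)
  expect_length(rois$nucleus, 4L)
  expect_equal(length(rois$artifact$A), 25L)
  expect_equal(length(rois$artifact$B), 25L)
  all_rois <- c(rois$vein, rois$nucleus,
                list(rois$brain, rois$artifact$A, rois$artifact$B))
  expect_true(all(vapply(all_rois, length, integer(1)) > 0))
  # pairwise disjoint
  flat <- unlist(all_rois)
  expect_equal(anyDuplicated(flat), 0L)
  # brain ROI sits in tissue-free slices of the reference
  expect_equal(mean(vol_data(ref)[rois$brain]), 0)
  # artifact ROIs are tissue-free
  expect_equal(max(abs(vol_data(ref)[c(rois$artifact$A, rois$artifact$B)])), 0)
  # vein ROI means reflect the partial-volume reference, ordered in chi_v
  st <- roi_stats(ref, rois)
  m <- st$mean[match(c("d0.70_chi0.10", "d0.70_chi0.20", "d0.70_chi0.30"),
                     st$roi)]
  expect_true(all(diff(m) > 0))
})

test_that("rasterization is deterministic and order-independent", {
  spec <- phantom_spec(n = c(64, 64, 64))
  r1 <- rasterize_phantom(spec)
  spec2 <- spec
  spec2$veins <- spec$veins[rev(seq_len(nrow(spec$veins))), ]
  r2 <- rasterize_phantom(spec2)
  expect_identical(vol_data(r1$chi), vol_data(r2$chi))
})
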