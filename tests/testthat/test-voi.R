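test_that("Otsu threshold maximizes between-class variance (exhaustive oracle)", {
  # independent exhaustive scan over the same 256-bin histogram
  otsu_oracle <- function(values, n_bins = 256) {
    rng <- range(values)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1), n_bins)
    mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
    best <- -Inf; best_k <- NA
    for (k in 1:n_bins) {
      lo <- bin <= k
      w0 <- mean(lo); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- mean(mids[bin[lo]]); mu1 <- mean(mids[bin[!lo]])
      v <- w0 * w1 * (mu0 - mu1)^2
      if (v > best + 1e-12) { best <- v; best_k <- k }
    }
    edges[best_k + 1]
  }
  bimodal <- c(rep(1, 100), rep(40, 100))
  t_pkg <- otsu_threshold(bimodal)
  expect_gt(t_pkg, 1); expect_lt(t_pkg, 40)
  expect_equal(t_pkg, otsu_oracle(bimodal))
  set.seed(42)
  for (r in 1:10) {
    x <- c(rnorm(120, 5, 1), rnorm(80, 20, 3))
    expect_equal(otsu_threshold(x), otsu_oracle(x))
  }
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
  expect_error(otsu_threshold(numeric(0)), "degenerate")
  t01 <- otsu_threshold(c(0, 1))
  expect_gt(t01, 0); expect_lt(t01, 1)
})

test_that("SUV scaling follows its definition and is linear in body mass", {
  img <- voxel_image(array(10, c(8, 8, 8)), 4.8, "kBq/mL")
  # concentration = injected/mass in matched units -> SUV 1
  suv1 <- suv_from_activity(voxel_image(array(7400 * 1000 / 80000, c(8, 8, 8)),
                                        4.8, "kBq/mL"), 7400, 80000)
  expect_equal(unname(suv1$data[1]), 1)
  a <- suv_from_activity(img, 7400, 40000)
  b <- suv_from_activity(img, 7400, 80000)
  expect_equal(b$data, 2 * a$data)
  # 10 kBq/mL, 7.4 GBq, 80 kg: SUV = 10 * 80000 / 7.4e6
  expect_equal(unname(b$data[1]), 10 * 80000 / 7.4e6)
  expect_error(suv_from_activity(img, -1, 100), "positive")
})

test_that("lesion segmentation recovers a blurred high-contrast lesion", {
  spec <- box_phantom_spec(lesion_radius_mm = 12.4)  # ~8 mL
  ph <- build_phantom(spec)
  blurred <- gaussian_blur(ph$reference, 3.53)
  suv <- suv_from_activity(blurred, 7400, 70000)
  mask <- segment_lesions(suv, ph$labels)
  truth <- ph$labels$lesion_mask
  dice <- dice_coefficient(mask, truth)
  expect_gt(dice, 0.5)
  # Dice equals the independent voxel-set computation
  expect_equal(dice, 2 * length(intersect(which(mask), which(truth))) /
                 (length(which(mask)) + length(which(truth))))
  expect_true(all(which(mask) %in% which(ph$labels$labels == 1)))
})

test_that("segmentation returns empty mask when nothing reaches the SUV cut", {
  ph <- build_phantom(box_phantom_spec())
  suv <- suv_from_activity(ph$reference, 7400, 70000)  # SUV ~0.24 everywhere
  expect_warning(m <- segment_lesions(suv, ph$labels), "empty lesion mask")
  expect_equal(sum(m), 0)
})

test_that("lesion components below the volume floor are dropped", {
  grid <- c(40, 40, 40); sp <- 4.8
  labels <- array(0L, grid); labels[5:36, 5:36, 5:36] <- 1L
  st <- data.frame(id = 1L, name = "bone", voxel_count = sum(labels == 1))
  st$volume_mL <- st$voxel_count * voxel_volume_mL(sp)
  lm <- site_label_map(labels, array(FALSE, grid), st, integer(0), sp)
  suv_arr <- array(0.3, grid)
  suv_arr[8:11, 8:11, 8:11] <- 8      # 64 voxels -> ~7 mL, kept
  suv_arr[30, 30, 30] <- 8            # 1 voxel -> 0.11 mL, dropped
  suv <- voxel_image(suv_arr, sp, "unitless")
  m <- segment_lesions(suv, lm, min_lesion_vol_mL = 1)
  expect_true(all(m[8:11, 8:11, 8:11]))
  expect_false(m[30, 30, 30])
})

test_that("marrow VOI construction follows erode-site minus dilate-lesion", {
  grid <- c(15, 15, 15)
  site <- array(FALSE, grid); site[6:10, 6:10, 6:10] <- TRUE  # 5-cube
  lesion <- array(FALSE, grid); lesion[8, 8, 8] <- TRUE
  params <- morphology_params()
  # lesion-free: VOI equals the eroded site mask
  expect_identical(build_rbm_voi(site, NULL, params), erode_mask(site, 1, 6))
  voi <- build_rbm_voi(site, lesion, params)
  # brute-force set arithmetic with the 6-connected cross
  shift_or <- function(m) {
    out <- m
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      s <- array(FALSE, dim(m))
      idx <- which(m, arr.ind = TRUE)
      nb <- sweep(idx, 2, o, `+`)
      ok <- nb[,1] >= 1 & nb[,1] <= dim(m)[1] & nb[,2] >= 1 & nb[,2] <= dim(m)[2] &
        nb[,3] >= 1 & nb[,3] <= dim(m)[3]
      s[nb[ok, , drop = FALSE]] <- TRUE
      out <- out | s
    }
    out
  }
  eroded <- !shift_or(!site)  # erosion = complement of dilated complement
  dil_les <- shift_or(lesion)
  expect_identical(voi, eroded & !dil_les)
  expect_equal(sum(voi), 27 - 7)  # 3-cube core minus the dilated center cross
  # invariant: VOI never intersects the dilated lesion
  expect_false(any(voi & dil_les))
  # site fully covered by the dilated lesion -> empty VOI
  big <- array(FALSE, grid); big[5:11, 5:11, 5:11] <- TRUE
  expect_equal(sum(build_rbm_voi(site, big, params)), 0)
})

test_that("surface distance: trivial geometry and all-pairs oracle", {
  grid <- c(20, 20, 20)
  a <- array(FALSE, grid); a[5, 5, 5] <- TRUE
  b <- array(FALSE, grid); b[8, 5, 5] <- TRUE  # 3 voxels along x
  expect_equal(surface_distance_mm(a, b, 4.8), 14.4)
  expect_equal(surface_distance_mm(a, a, 4.8), 0)
  expect_error(surface_distance_mm(a, array(FALSE, grid), 4.8), "nonempty")
  set.seed(7)
  blob_a <- array(FALSE, grid); blob_b <- array(FALSE, grid)
  blob_a[cbind(sample(2:8, 12, TRUE), sample(2:8, 12, TRUE), sample(2:8, 12, TRUE))] <- TRUE
  blob_b[cbind(sample(13:19, 12, TRUE), sample(13:19, 12, TRUE), sample(13:19, 12, TRUE))] <- TRUE
  # all-pairs minimum over surface voxels, computed independently
  sa <- which(blob_a & !erode_mask(blob_a, 1, 6))
  sb <- which(blob_b & !erode_mask(blob_b, 1, 6))
  pa <- arrayInd(sa, grid); pb <- arrayInd(sb, grid)
  dmin <- min(apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2)))))
  expect_equal(surface_distance_mm(blob_a, blob_b, 2.0), dmin * 2.0)
})

test_that("site classification: lesion presence, 30 mm rule, threshold monotonicity", {
  grid <- c(60, 60, 20); sp <- 2
  labels <- array(0L, grid)
  labels[5:10, 5:10, 5:10] <- 1L    # hosts the lesion
  labels[16:20, 5:10, 5:10] <- 2L   # 5 voxels gap from lesion -> 10 mm
  labels[36:40, 5:10, 5:10] <- 3L   # 25 voxels gap -> 50 mm
  lesion <- array(FALSE, grid); lesion[10, 5:10, 5:10] <- TRUE
  st <- data.frame(id = 1:3, name = c("host", "near", "far"),
                   voxel_count = c(sum(labels == 1), sum(labels == 2), sum(labels == 3)))
  st$volume_mL <- st$voxel_count * voxel_volume_mL(sp)
  lm <- site_label_map(labels, lesion, st, integer(0), sp)
  m30 <- classify_sites(lm, lesion, morphology_params(distance_threshold_mm = 30))
  expect_equal(unname(m30), c(1L, 2L, 3L))
  m60 <- classify_sites(lm, lesion, morphology_params(distance_threshold_mm = 60))
  expect_equal(unname(m60["3"]), 2L)
  # method-2 count is non-decreasing in the threshold
  counts <- sapply(c(5, 15, 30, 45, 60), function(thr)
    sum(classify_sites(lm, lesion,
                       morphology_params(distance_threshold_mm = thr)) == 2L))
  expect_true(all(diff(counts) >= 0))
  # classification is a partition: exactly one method per site
  expect_true(all(m30 %in% 1:3))
  expect_equal(length(m30), nrow(st))
})

test_that("VOI evaluation: mean x volume, volume gate, nesting, linearity", {
  grid <- c(20, 20, 20); sp <- 2 # 8 mm^3 voxels = 0.008 mL
  img <- voxel_image(array(2, grid), sp, "kBq/mL")
  voi <- array(FALSE, grid); voi[seq_len(1250)] <- TRUE  # 1250 * 0.008 = 10 mL
  rec <- evaluate_voi(voi, img, min_volume_mL = 1)
  expect_equal(rec$volume_mL, 10)
  expect_equal(rec$total_MBq, 2 * 10 / 1000)  # 20 kBq
  expect_true(rec$included)
  small <- array(FALSE, grid); small[seq_len(112)] <- TRUE  # 0.896 mL
  expect_false(evaluate_voi(small, img, min_volume_mL = 1)$included)
  expect_false(evaluate_voi(array(FALSE, grid), img)$included)
  # linearity: scaling the image scales total activity
  rec2 <- evaluate_voi(voi, with_data(img, img$data * 3), min_volume_mL = 1)
  expect_equal(rec2$total_MBq, 3 * rec$total_MBq)
})

test_that("retained VOI sets are nested across volume thresholds", {
  specs <- lapply(1:2, sample_phantom_spec)
  rec <- run_rc_experiment(specs, corrections = "none",
                           volume_thresholds_mL = c(1, 5, 15),
                           regimes = list(acquisition_regime(poisson_noise = FALSE)))
  key <- function(thr) {
    d <- rec[rec$volume_threshold_mL == thr, ]
    paste(d$phantom_id, d$site_id)
  }
  expect_true(all(key(15) %in% key(5)))
  expect_true(all(key(5) %in% key(1)))
})
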