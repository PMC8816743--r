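# Mitochondrial segmentation, somatodendritic ROIs, intensity fold-changes.

test_that("blank images give empty masks, not errors", {
  st <- matrix_stack(matrix(0, 40, 40), channel = "MITO")
  expect_true(all(segment_mitochondria(st, "MITO") == 0))
})

test_that("global Otsu segmentation is invariant to additive offsets", {
  sc <- generate_scene(quick_cfg(cluster_present = TRUE, seed = 51))
  m0 <- segment_mitochondria(sc$stack)
  shifted <- sc$stack
  shifted$pixels <- shifted$pixels + 123.4
  m1 <- segment_mitochondria(shifted)
  expect_identical(m0, m1)
})

test_that("noise-free puncta are recovered almost completely by the mask", {
  cfg <- no_noise(quick_cfg(n_dendrites = 0, baseline_mito_density = 0.3,
                            seed = 52))
  sc <- generate_scene(cfg)
  mask <- segment_mitochondria(sc$stack)
  truth <- sc$truth$puncta
  sig_px <- cfg$mito_sigma_um / cfg$pixel_size_um
  # ground-truth support: pixels within 1 sigma of a punctum centre
  covered <- vapply(seq_len(nrow(truth)), function(i) {
    xs <- round(truth$x_px[i] + (-1:1)); ys <- round(truth$y_px[i] + (-1:1))
    mean(mask[cbind(rep(ys, 3) + 1, rep(xs, each = 3) + 1)])
  }, 0)
  expect_gte(mean(covered), 0.95)
})

test_that("segmentation config validates method arguments", {
  expect_error(segmentation_config(method = "fixed"), "fixed_threshold")
  expect_error(segmentation_config(fixed_threshold = 5), "only valid")
  cfgf <- segmentation_config(method = "fixed", fixed_threshold = 50)
  st <- matrix_stack(matrix(c(0, 100), 20, 20), channel = "MITO")
  expect_true(all(segment_mitochondria(st, "MITO", cfgf) %in% c(0, 1)))
})

test_that("soma detection finds the true soma and fails on blank MAP2", {
  sc <- generate_scene(quick_cfg(seed = 53))
  sr <- somatodendritic_rois(sc$stack)
  expect_length(sr$somata, 1)
  d_px <- sqrt(sum((sr$somata[[1]]$centroid_px -
                      sc$truth$soma_center_px)^2))
  expect_lt(d_px * sc$stack$pixel_size_um, sc$truth$soma_radius_um)
  expect_true(any(sr$dendrite_mask > 0))

  blank <- sc$stack
  blank$pixels[1, 1, , ] <- 0
  expect_error(somatodendritic_rois(blank), "no soma")
})

test_that("somatic fold-change reproduces the worked arithmetic", {
  # soma mean 150, background 50, control corrected mean 10 -> normalized 10
  mk <- function(soma_val, cid, cond) {
    m <- matrix(50, 40, 40)
    m[15:25, 15:25] <- soma_val
    list(stack = matrix_stack(m, channel = "TAU"), cell_id = cid,
         condition = cond, replicate_id = "r1",
         soma_roi = roi_annotation(cid, "soma",
                                   cbind(c(14, 25, 25, 14), c(14, 14, 25, 25))),
         background_roi = roi_annotation(cid, "background",
                                         cbind(c(1, 8, 8, 1), c(1, 1, 8, 8))))
  }
  cells <- list(mk(60, "ctrl1", "Ctrl"), mk(150, "t1", "Treated"))
  sm <- somatic_intensity_foldchange(cells, control = "Ctrl")
  expect_equal(sm$normalized[sm$cell_id == "ctrl1"], 1)
  expect_equal(sm$normalized[sm$cell_id == "t1"], 10)
})

test_that("fold-changes are invariant to global offset and gain", {
  coh <- generate_cohort(quick_cfg(tau_somatic_fold = 3), 4, seed = 54)
  mkcells <- function(f) lapply(seq_along(coh$scenes), function(i) {
    s <- coh$scenes[[i]]
    st <- s$stack; st$pixels <- f(st$pixels)
    list(stack = st, cell_id = s$truth$cell_id,
         condition = if (i <= 2) "Ctrl" else "Treated",
         replicate_id = "r1", soma_roi = s$annotations$rois[[1]],
         background_roi = s$annotations$rois[[2]])
  })
  base <- somatic_intensity_foldchange(mkcells(identity), control = "Ctrl")
  off <- somatic_intensity_foldchange(mkcells(function(p) p + 20),
                                      control = "Ctrl")
  gain <- somatic_intensity_foldchange(mkcells(function(p) p * 3.7),
                                       control = "Ctrl")
  expect_equal(off$normalized, base$normalized, tolerance = 1e-9)
  expect_equal(gain$normalized, base$normalized, tolerance = 1e-9)
  expect_equal(mean(base$normalized[base$condition == "Ctrl"]), 1)
})

test_that("polarity index is exact on constructed soma/dendrite means", {
  m <- matrix(0, 40, 40)
  m[5:15, 5:15] <- 80          # soma
  m[30:32, 5:35] <- 40         # dendrite
  st <- matrix_stack(m, channel = "MAP2")
  soma <- matrix(0, 40, 40); soma[5:15, 5:15] <- 1
  dend <- matrix(0, 40, 40); dend[30:32, 5:35] <- 1
  expect_equal(map2_polarity_index(st, soma, dend,
                                   background_roi = roi_annotation(
                                     "c", "background",
                                     cbind(c(20, 25, 25, 20),
                                           c(20, 20, 25, 25)))), 2)
  m2 <- m; m2[30:32, 5:35] <- 80
  st2 <- matrix_stack(m2, channel = "MAP2")
  expect_equal(map2_polarity_index(st2, soma, dend,
                                   background_roi = roi_annotation(
                                     "c", "background",
                                     cbind(c(20, 25, 25, 20),
                                           c(20, 20, 25, 25)))), 1)
  expect_error(map2_polarity_index(st, soma, matrix(0, 40, 40)), "empty")
})

test_that("MAP2 polarity is recovered from generated scenes", {
  pis <- vapply(55:58, function(s) {
    sc <- generate_scene(scene_config(seed = s))
    sr <- somatodendritic_rois(sc$stack)
    map2_polarity_index(sc$stack, sr$somata[[1]]$mask, sr$dendrite_mask)
  }, 0)
  expect_lt(abs(mean(pis) - 2.3) / 2.3, 0.1)
})

test_that("ROI time series normalises to frame 1 and tracks scripted drops", {
  # constant movie -> flat 1.0
  arr <- array(10, dim = c(5, 1, 30, 30))
  arr[, 1, 3:11, 3:11] <- 110
  tl <- image_stack(arr, "TMRM", 0.25, frame_interval_s = 6)
  roiA <- roi_annotation("c", "custom", cbind(c(2, 10, 10, 2), c(2, 2, 10, 10)))
  roiB <- roi_annotation("c", "custom", cbind(c(15, 25, 25, 15),
                                              c(15, 15, 25, 25)))
  bg <- roi_annotation("c", "background", cbind(c(26, 29, 29, 26),
                                                c(2, 2, 5, 5)))
  ts0 <- roi_timeseries(tl, list(roiA), 1, background_roi = bg)
  expect_true(all(abs(ts0$relative - 1) < 1e-9))

  # ROI-A signal drops 80% from frame 3 on; ROI-B stays constant
  arr2 <- array(10, dim = c(5, 1, 30, 30))
  arr2[, 1, 3:11, 3:11] <- 110
  arr2[, 1, 16:26, 16:26] <- 110
  arr2[3:5, 1, 3:11, 3:11] <- 10 + 0.2 * 100
  tl2 <- image_stack(arr2, "TMRM", 0.25, frame_interval_s = 6)
  ts <- roi_timeseries(tl2, list(roiA, roiB), 1, background_roi = bg)
  relA <- ts$relative[seq(1, 10, by = 2)]
  relB <- ts$relative[seq(2, 10, by = 2)]
  expect_equal(relA[4:5], c(0.2, 0.2), tolerance = 1e-9)
  expect_true(all(abs(relB - 1) < 1e-9))

  # global exponential bleaching affects both ROIs identically
  bleach <- exp(-0.1 * (0:4))
  arr3 <- array(0, dim = c(5, 1, 30, 30))
  for (t in 1:5) {
    arr3[t, 1, , ] <- 10 * bleach[t]
    arr3[t, 1, 3:11, 3:11] <- 100 * bleach[t]
    arr3[t, 1, 16:26, 16:26] <- 100 * bleach[t]
  }
  tl3 <- image_stack(arr3, "TMRM", 0.25, frame_interval_s = 6)
  ts3 <- roi_timeseries(tl3, list(roiA, roiB), 1, background_roi = bg)
  expect_equal(ts3$relative[ts3$roi == "custom"][seq(1, 10, by = 2)],
               ts3$relative[ts3$roi == "custom"][seq(2, 10, by = 2)],
               tolerance = 1e-9)

  expect_error(roi_timeseries(matrix_stack(matrix(1, 5, 5)), list(roiA), 1),
               "time axis")
})
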