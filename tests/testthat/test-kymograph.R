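# Kymograph construction, event detection and per-cell fractions.

test_that("a stationary punctum is a vertical band and never an event", {
  cfg <- no_noise(movie_cfg(71, cluster_present = TRUE))
  tl <- generate_timelapse(cfg, event_script(), duration_s = 60,
                           interval_s = 3)
  ky <- build_kymograph(tl$stack, tl$annotations$paths[[1]])
  red <- ky$red$matrix
  # band: each occupied distance row is occupied in every frame
  occupied <- rowSums(red > 0.5 * max(red)) > 0
  expect_true(any(occupied))
  band_rows <- which(occupied)
  expect_true(all(red[band_rows, ] > 0.5 * max(red) * 0.5))
  ev <- detect_and_classify_events(ky, tl$truth$cluster_span)
  expect_equal(nrow(ev), 0L)
})

test_that("an empty movie yields an all-zero kymograph", {
  arr <- array(0, dim = c(4, 1, 30, 60))
  tl <- image_stack(arr, "green", 0.25, frame_interval_s = 2)
  ky <- build_kymograph(tl, straight_path("c", 2, 55, 15))
  expect_true(all(ky$green$matrix == 0))
})

test_that("single-frame input is rejected", {
  st <- matrix_stack(matrix(0, 30, 30))
  expect_error(build_kymograph(st, straight_path("c", 2, 25, 15)),
               "time axis|single-frame")
})

test_that("a scripted ridge has the scripted slope", {
  cfg <- no_noise(movie_cfg(72, cluster_present = FALSE))
  scr <- event_script(t_start_s = 0, x_start_um = 5,
                      velocity_um_per_s = 0.5, duration_s = 30,
                      origin = "other", channel = "green", config = cfg)
  tl <- generate_timelapse(cfg, scr, duration_s = 30, interval_s = 3)
  ky <- build_kymograph(tl$stack, tl$annotations$paths[[1]])
  ev <- detect_and_classify_events(ky, c(0, 12.5))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$speed_um_s, 0.5, tolerance = 0.05)
  expect_equal(ev$direction, "anterograde")
})

test_that("events below the displacement gate are dropped", {
  cfg <- no_noise(movie_cfg(73, cluster_present = FALSE))
  scr <- event_script(t_start_s = 0, x_start_um = 8,
                      velocity_um_per_s = 0.15, duration_s = 10,
                      origin = "other", channel = "green", config = cfg)
  tl <- generate_timelapse(cfg, scr, duration_s = 30, interval_s = 2)
  ky <- build_kymograph(tl$stack, tl$annotations$paths[[1]])
  ev <- detect_and_classify_events(ky, c(0, 12.5),
                                   min_displacement_um = 2)
  expect_equal(nrow(ev), 0L)
})

test_that("scripted events are recovered with direction and origin", {
  for (seed in 74:78) {
    cfg <- no_noise(movie_cfg(seed))
    scr <- random_event_script(cfg, 5, duration_s = 240, p_cluster = 0.3,
                               seed = seed)
    tl <- generate_timelapse(cfg, scr, duration_s = 240, interval_s = 3)
    ky <- build_kymograph(tl$stack, tl$annotations$paths[[1]])
    ev <- detect_and_classify_events(ky, tl$truth$cluster_span)
    sdf <- as.data.frame(scr)
    sdf$dir <- ifelse(sdf$velocity_um_per_s > 0, "anterograde",
                      "retrograde")
    expect_equal(nrow(ev), nrow(sdf))
    expect_identical(sort(paste(ev$direction, ev$origin)),
                     sort(paste(sdf$dir, sdf$origin)))
  }
})

test_that("time reversal swaps anterograde and retrograde exactly", {
  cfg <- no_noise(movie_cfg(79))
  scr <- random_event_script(cfg, 6, duration_s = 240, p_cluster = 0,
                             seed = 80)
  tl <- generate_timelapse(cfg, scr, duration_s = 240, interval_s = 3)
  ky <- build_kymograph(tl$stack, tl$annotations$paths[[1]])
  ev <- detect_and_classify_events(ky, tl$truth$cluster_span)
  rev_ky <- lapply(ky, function(k) {
    k$matrix <- k$matrix[, rev(seq_len(ncol(k$matrix)))]
    k
  })
  rev_ev <- detect_and_classify_events(rev_ky, tl$truth$cluster_span)
  expect_equal(nrow(rev_ev), nrow(ev))
  expect_equal(sum(rev_ev$direction == "anterograde"),
               sum(ev$direction == "retrograde"))
  expect_equal(sum(rev_ev$direction == "retrograde"),
               sum(ev$direction == "anterograde"))
})

test_that("a missing red channel downgrades origins with a warning", {
  cfg <- no_noise(movie_cfg(81, cluster_present = FALSE))
  scr <- event_script(t_start_s = 0, x_start_um = 4,
                      velocity_um_per_s = 0.5, duration_s = 25,
                      origin = "other", channel = "green", config = cfg)
  tl <- generate_timelapse(cfg, scr, duration_s = 30, interval_s = 3)
  ky <- build_kymograph(tl$stack, tl$annotations$paths[[1]],
                        channels = "green")
  expect_warning(ev <- detect_and_classify_events(ky, c(0, 12.5)),
                 "no red channel")
  expect_true(all(ev$origin == "other"))
})

test_that("event fractions are per-cell and exclude zero-event cells", {
  mk <- function(n_cluster, n_other, n_antero) {
    n <- n_cluster + n_other
    data.frame(channel = "x", t_start_s = 0, t_end_s = 1, x_start_um = 0,
               x_end_um = 1, displacement_um = 1, speed_um_s = 1,
               direction = c(rep("anterograde", n_antero),
                             rep("retrograde", n - n_antero)),
               origin = c(rep("cluster", n_cluster),
                          rep("other", n_other)),
               stringsAsFactors = FALSE)
  }
  fr <- event_fractions(list(cellA = mk(2, 8, 6),
                             cellB = mk(1, 1, 1)[0, ],
                             cellC = mk(1, 4, 3)))
  expect_equal(fr$n_excluded, 1L)
  expect_equal(fr$per_cell$cluster_fraction[fr$per_cell$cell_id == "cellA"],
               0.2)
  expect_equal(fr$per_cell$other_fraction[fr$per_cell$cell_id == "cellA"],
               0.8)
  expect_true(all(abs(fr$per_cell$cluster_fraction +
                        fr$per_cell$other_fraction - 1) < 1e-12))
  expect_true(all(abs(fr$per_cell$anterograde_fraction +
                        fr$per_cell$retrograde_fraction - 1) < 1e-12))
  expect_equal(unname(fr$cohort["cluster_fraction"]), mean(c(0.2, 0.2)))
  expect_error(event_fractions(list(a = mk(1, 1, 1)[0, ])), "excluded")
})
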