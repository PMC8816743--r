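# Line-profile extraction, sliding mean, AIS-start detection, alignment.

test_that("profile of a constant image is constant for any path", {
  st <- matrix_stack(matrix(7.5, 60, 60))
  p <- path_annotation("c1", "axon", cbind(c(5, 20, 40, 50), c(5, 25, 18, 40)))
  pr <- extract_profile(st, 1, p)
  expect_true(all(abs(pr$values - 7.5) < 1e-9))
})

test_that("a single bright pixel peaks at its arclength", {
  m <- matrix(0, 60, 60)
  m[31, 41] <- 100    # (x, y) = (40, 30)
  st <- matrix_stack(m, pixel_size_um = 0.5)
  p <- straight_path("c1", 10, 55, 30)
  pr <- extract_profile(st, 1, p, width_um = 0.5, step_um = 0.5)
  peak_um <- profile_positions(pr)[which.max(pr$values)]
  expect_equal(peak_um, (40 - 10) * 0.5)
})

test_that("wide line over a narrow stripe averages by area", {
  m <- matrix(0, 80, 80)
  m[39:41, ] <- 10          # 3-px-high horizontal stripe of value 10
  st <- matrix_stack(m, pixel_size_um = 1)
  p <- straight_path("c1", 10, 70, 39)
  # 9-px-wide line across a 3-px stripe: plateau = 10 * 3 / 9
  pr <- extract_profile(st, 1, p, width_um = 8, step_um = 1)
  mid <- pr$values[20:40]
  expect_equal(mean(mid), 10 * 3 / 9, tolerance = 0.05)
})

test_that("path leaving the image names the offending vertex", {
  st <- matrix_stack(matrix(0, 20, 20))
  p <- path_annotation("c1", "axon", cbind(c(5, 30), c(5, 5)))
  expect_error(extract_profile(st, 1, p), "vertex 2")
})

test_that("sliding mean is exact on constant, affine and impulse profiles", {
  const <- line_profile("c", "x", 0.1, rep(3, 50))
  expect_equal(sliding_mean(const, 1)$values, rep(3, 50))

  x <- seq(0, 10, by = 0.1)
  lin <- line_profile("c", "x", 0.1, 2 * x + 1)
  sm <- sliding_mean(lin, 1)$values
  interior <- 6:96
  expect_equal(sm[interior], (2 * x + 1)[interior], tolerance = 1e-12)

  imp <- line_profile("c", "x", 0.1, c(rep(0, 30), 1, rep(0, 30)))
  smi <- sliding_mean(imp, 1)$values
  expect_equal(smi[26:36], rep(1 / 11, 11))
  expect_equal(sum(smi[26:36] > 0), 11L)

  expect_error(sliding_mean(const, 0.05), "smaller than the sample step")
})

test_that("AIS start matches the closed forms for step and ramp profiles", {
  x <- seq(0, 10, by = 0.1)
  step <- line_profile("c", "AIS", 0.1, ifelse(x >= 5, 100, 0))
  expect_equal(detect_ais_start(step)$start_um, 4.8, tolerance = 0.05)

  ramp <- line_profile("c", "AIS", 0.1, 10 * x)
  expect_equal(detect_ais_start(ramp)$start_um, 3.0, tolerance = 0.05)
})

test_that("AIS detection is gain-invariant but offset-sensitive", {
  x <- seq(0, 10, by = 0.1)
  prof <- line_profile("c", "AIS", 0.1, ifelse(x >= 5, 100, 0))
  scaled <- line_profile("c", "AIS", 0.1, prof$values * 37.5)
  expect_identical(detect_ais_start(prof)$start_um,
                   detect_ais_start(scaled)$start_um)
  offset <- line_profile("c", "AIS", 0.1, prof$values + 50)
  # +50 lifts the pre-step plateau above 30% of max: detection moves to 0
  expect_warning(off_start <- detect_ais_start(offset)$start_um)
  expect_false(off_start == detect_ais_start(prof)$start_um)
})

test_that("degenerate AIS profiles are flagged", {
  x <- seq(0, 10, by = 0.1)
  dec <- line_profile("c", "AIS", 0.1, 100 - 5 * x)
  expect_warning(st <- detect_ais_start(dec), "arclength 0")
  expect_equal(st$start_um, 0)
  expect_true(st$at_origin)
  zero <- line_profile("c", "AIS", 0.1, rep(0, 30))
  expect_error(detect_ais_start(zero), "no AIS detected")
})

test_that("binary presence profiles mark punctum support only", {
  st <- matrix_stack(matrix(0, 40, 200), pixel_size_um = 0.25)
  empty <- binary_presence_profile(get_channel(st, 1),
                                   straight_path("c", 2, 190, 20), 0.25)
  expect_true(all(empty$values == 0))

  full <- binary_presence_profile(matrix(1, 40, 200),
                                  straight_path("c", 2, 190, 20), 0.25)
  expect_true(all(full$values == 1))

  m <- matrix(0, 40, 200)
  # disc of radius 0.6 um (2.4 px) at x = 50 px (arclength (50-2)*0.25 = 12)
  for (xx in 45:55) for (yy in 15:25) {
    if ((xx - 50)^2 + (yy - 20)^2 <= 2.4^2) m[yy + 1, xx + 1] <- 1
  }
  pr <- binary_presence_profile(m, straight_path("c", 2, 190, 20), 0.25)
  pos <- profile_positions(pr)
  on <- pos[pr$values == 1]
  expect_true(all(abs(on - 12) < 1.0))
  expect_true(length(on) >= 3)

  expect_error(binary_presence_profile(matrix(0.5, 4, 4),
                                       straight_path("c", 0, 3, 2), 1),
               "not binary")
})

test_that("alignment shifts profiles onto a common AIS-relative axis", {
  shape <- c(rep(0, 10), rep(1, 10), rep(0, 10))
  p1 <- line_profile("a", "m", 1, c(shape, 0, 0))
  p2 <- line_profile("b", "m", 1, c(0, 0, shape))
  s1 <- structure(list(cell_id = "a", start_um = 10), class = "ais_start")
  s2 <- structure(list(cell_id = "b", start_um = 12), class = "ais_start")
  al <- align_and_average(list(p1, p2), list(s1, s2), c("r1", "r1"),
                          min_cells = 2)
  expect_true(all(al$mean[al$axis_um >= 0 & al$axis_um <= 9] == 1))
  expect_true(all(al$mean[al$axis_um < 0 | al$axis_um > 9] == 0))
})

test_that("replicate-weighted mean weights replicates, not cells", {
  ones <- lapply(1:10, function(i) line_profile(paste0("a", i), "m", 1,
                                                rep(1, 20)))
  zeros <- lapply(1:2, function(i) line_profile(paste0("b", i), "m", 1,
                                                rep(0, 20)))
  starts <- lapply(1:12, function(i) {
    structure(list(cell_id = "x", start_um = 5), class = "ais_start")
  })
  al <- align_and_average(c(ones, zeros), starts,
                          c(rep("A", 10), rep("B", 2)), min_cells = 3)
  expect_true(all(abs(al$mean - 0.5) < 1e-12))   # not 10/12
})

test_that("positions covered by fewer than min_cells are dropped", {
  long <- line_profile("a", "m", 1, rep(1, 30))
  short1 <- line_profile("b", "m", 1, rep(1, 15))
  short2 <- line_profile("c", "m", 1, rep(1, 15))
  starts <- lapply(1:3, function(i) {
    structure(list(cell_id = "x", start_um = 0), class = "ais_start")
  })
  al <- align_and_average(list(long, short1, short2), starts,
                          rep("r1", 3), min_cells = 3)
  expect_equal(max(al$axis_um), 14)   # tail covered by 1 cell is absent
})

test_that("region means are exact on constructed windows and translation-invariant", {
  # all-1 in [-5, 5], all-0 in [10, 20]
  vals <- rep(0, 41)
  pos0 <- -10
  vals[(-5 - pos0 + 1):(5 - pos0 + 1)] <- 1
  profs <- lapply(1:4, function(i) line_profile(paste0("c", i), "m", 1, vals))
  starts <- lapply(1:4, function(i) {
    structure(list(cell_id = "x", start_um = 10), class = "ais_start")
  })
  al <- align_and_average(profs, starts, c("r1", "r1", "r2", "r2"),
                          min_cells = 2)
  rm_ <- region_means(al)
  ov <- attr(rm_, "overall")
  expect_equal(unname(ov["proximal"]), 1)
  expect_equal(unname(ov["central"]), 0)

  # shifting all starts and all windows by the same offset changes nothing
  starts2 <- lapply(starts, function(s) { s$start_um <- s$start_um - 3; s })
  al2 <- align_and_average(profs, starts2, c("r1", "r1", "r2", "r2"),
                           min_cells = 2)
  w2 <- lapply(default_windows(), function(w) w + 3)
  ov2 <- attr(region_means(al2, w2), "overall")
  expect_equal(ov2, ov)

  expect_error(region_means(al, list(far = c(900, 910))), "outside")
})
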