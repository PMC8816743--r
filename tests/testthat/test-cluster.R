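# Cluster classification, cohort ratio, diameter/area, mass-vs-volume.

# profiles for a cell with controllable proximal/central presence and
# proximal brightness; step 0.5 um, 80 um long, AIS start 10 um
toy_profiles <- function(prox_presence = 0.6, central_presence = 0.05,
                         prox_gain = 3, base_amp = 100) {
  pos <- seq(0, 80, by = 0.5)
  start <- 10
  # 10-slot repeating occupancy pattern: filling k of 10 slots gives a
  # presence fraction of k/10 in each region
  slot <- (seq_along(pos) - 1) %% 10
  k <- function(p) floor(p * 10 + 0.5)
  prox <- abs(pos - start) <= 7.5
  cen <- pos >= start + 10 & pos <= start + 20
  distal <- pos > start + 20
  presence <- as.numeric((prox & slot < k(prox_presence)) |
                           (cen & slot < k(central_presence)) |
                           (distal & slot < 6))
  intensity <- rep(5, length(pos))
  intensity[presence == 1 & !prox] <- base_amp
  intensity[presence == 1 & prox] <- base_amp * prox_gain
  list(presence = line_profile("c", "presence", 0.5, presence),
       intensity = line_profile("c", "MITO", 0.5, intensity),
       start = start)
}

test_that("category follows the number of criteria met", {
  tp <- toy_profiles()
  call3 <- classify_cluster(tp$presence, tp$intensity, tp$start)
  expect_true(call3$c1 && call3$c2 && call3$c3)
  expect_equal(call3$category, "+")

  # kill criterion 3 only (no brightness gain)
  tp2 <- toy_profiles(prox_gain = 1)
  call2 <- classify_cluster(tp2$presence, tp2$intensity, tp2$start)
  expect_equal(sum(call2$c1, call2$c2, call2$c3), 2)
  expect_equal(call2$category, "~")

  # kill criteria 2 and 3 (central as full as proximal, no gain)
  tp1 <- toy_profiles(central_presence = 0.6, prox_gain = 1)
  call1 <- classify_cluster(tp1$presence, tp1$intensity, tp1$start)
  expect_lte(sum(call1$c1, call1$c2, call1$c3), 1)
  expect_equal(call1$category, "-")
})

test_that("profiles too short for the central window are marked invalid", {
  short <- line_profile("c", "m", 1, rep(1, 15))
  call <- classify_cluster(short, short, 5)
  expect_false(call$valid)
  expect_true(is.na(call$category))
  sm <- summarize_cluster_calls(list(call,
                                     classify_cluster(toy_profiles()$presence,
                                                      toy_profiles()$intensity,
                                                      10)))
  expect_equal(sm$n_excluded, 1L)
})

test_that("classification is invariant to multiplicative gain", {
  for (gain in c(0.1, 7, 250)) {
    tp <- toy_profiles()
    scaled <- line_profile("c", "MITO", 0.5, tp$intensity$values * gain)
    a <- classify_cluster(tp$presence, tp$intensity, tp$start)
    b <- classify_cluster(tp$presence, scaled, tp$start)
    expect_identical(a[c("c1", "c2", "c3", "category")],
                     b[c("c1", "c2", "c3", "category")])
  }
})

test_that("raising proximal amplitudes never demotes a positive call", {
  set.seed(60)
  for (i in 1:200) {
    tp <- toy_profiles(prox_presence = runif(1, 0.35, 0.9),
                       central_presence = runif(1, 0, 0.12),
                       prox_gain = runif(1, 1.6, 5))
    a <- classify_cluster(tp$presence, tp$intensity, tp$start)
    boost <- tp$intensity$values
    pos <- profile_positions(tp$intensity)
    sel <- abs(pos - tp$start) <= 7.5
    boost[sel] <- boost[sel] * runif(1, 1, 4)
    b <- classify_cluster(tp$presence,
                          line_profile("c", "MITO", 0.5, boost), tp$start)
    if (a$category == "+") expect_equal(b$category, "+")
    expect_gte(b$n_met, a$n_met)
  }
})

test_that("the cohort ratio formula matches its fixtures", {
  r1 <- cluster_ratio(4, 0, 0)
  expect_equal(r1$printed_ratio, 1)
  expect_equal(r1$positive_fraction, 1)

  r2 <- cluster_ratio(3, 2, 5)
  expect_equal(r2$printed_ratio, 2.5)
  expect_equal(r2$positive_fraction, 0.4)

  r3 <- cluster_ratio(0, 0, 7)
  expect_true(is.na(r3$printed_ratio))
  expect_equal(r3$positive_fraction, 0)

  set.seed(61)
  for (i in 1:50) {
    r <- cluster_ratio(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    if (!is.na(r$printed_ratio)) {
      expect_equal(r$printed_ratio * r$positive_fraction, 1)
    }
  }
  expect_error(cluster_ratio(0, 0, 0), "positive")
})

test_that("cross-sectional area follows (x/2)^2 * 0.6 * pi", {
  expect_equal(cross_section_area(0), 0)
  expect_equal(cross_section_area(2), 0.6 * pi, tolerance = 1e-12)
  expect_equal(cross_section_area(1.5), (1.5 / 2)^2 * 0.6 * pi)
})

test_that("FWHM diameters recover the rendered tapering width", {
  cfg <- no_noise(quick_cfg(seed = 62, n_dendrites = 0))
  sc <- generate_scene(cfg)
  dp <- diameter_and_area_profile(sc$stack, sc$annotations$paths[[1]],
                                  step_um = 1)
  interior <- dp$arclength_um >= 2 & dp$arclength_um <= 45 & !dp$skipped
  expected <- cfg$axon_width_um *
    (1 - 0.4 * pmin(dp$arclength_um[interior] / sc$truth$axon_length_um, 1))
  expect_true(all(abs(dp$diameter_um[interior] - expected) <
                    cfg$pixel_size_um))
  expect_equal(dp$area_um2[interior],
               (dp$diameter_um[interior] / 2)^2 * 0.6 * pi)
})

test_that("mass vs volume curves are normalised to their first point", {
  v <- line_profile("c", "VOL", 1, seq(100, 60, length.out = 41))
  m_same <- line_profile("c", "MITO", 1, seq(100, 60, length.out = 41))
  mv <- mass_vs_volume_profile(m_same, v, 5)
  expect_equal(mv$mito_rel, mv$volume_rel)
  expect_equal(mv$mito_rel[1], 1)
  expect_equal(mv$volume_rel[1], 1)

  # cluster scene: the mass/volume ratio peaks inside the proximal window
  cfg <- no_noise(quick_cfg(seed = 63, n_dendrites = 0,
                            cluster_present = TRUE))
  sc <- generate_scene(cfg)
  path <- sc$annotations$paths[[1]]
  mito <- extract_profile(sc$stack, "MITO", path, step_um = 1)
  vol <- extract_profile(sc$stack, "VOL", path, step_um = 1)
  st <- sc$truth$ais_start_um
  mv2 <- mass_vs_volume_profile(mito, vol, st)
  peak_pos <- mv2$position_um[which.max(mv2$ratio)]
  expect_lte(abs(peak_pos), cfg$cluster_window_um)

  bad <- line_profile("c", "MITO", 1, c(0, rep(1, 40)))
  expect_error(mass_vs_volume_profile(bad, v, 0), "positive")
})
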