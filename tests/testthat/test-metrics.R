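test_that("frequency collapse averages the band rows", {
  m <- allo_map_init(1:4)
  expect_equal(as.numeric(collapse_spatial(m)), rep(1 / 360, 360))
  # identical single-peak rows survive unchanged
  row <- dnorm(0:359, 100, 5); row <- row / sum(row)
  m$pdf <- matrix(row, 4, 360, byrow = TRUE)
  expect_equal(as.numeric(collapse_spatial(m)), row)
  # half the bands at 0, half at 45 -> equal bimodal profile
  r0 <- dnorm(circ_dist_deg(0:359, 0), 0, 4)
  r45 <- dnorm(circ_dist_deg(0:359, 45), 0, 4)
  m$pdf <- rbind(r0 / sum(r0), r0 / sum(r0), r45 / sum(r45), r45 / sum(r45))
  prof <- as.numeric(collapse_spatial(m))
  expect_equal(prof[1], prof[46], tolerance = 1e-12)
  rep_ <- find_two_peaks(prof)
  expect_setequal(rep_$angle_deg, c(0, 45))
})

test_that("peak finding ranks by prominence with stated tie-breaks", {
  v <- rep(0.1, 360)
  v[31] <- 1                                       # delta at 30
  rep1 <- find_two_peaks(v)
  expect_equal(rep1$angle_deg[1], 30)
  # two equal peaks: smaller angle first
  v2 <- rep(0.1, 360); v2[1] <- 1; v2[46] <- 1
  rep2 <- find_two_peaks(v2)
  expect_equal(rep2$angle_deg, c(0, 45))
  # flat profile -> empty, flagged
  rep3 <- find_two_peaks(rep(0.3, 360))
  expect_equal(nrow(rep3), 0L)
  expect_true(isTRUE(attr(rep3, "flat")))
  # a peak straddling the wrap point is found once
  v4 <- dnorm(circ_dist_deg(0:359, 359), 0, 6)
  expect_equal(find_two_peaks(v4)$angle_deg[1], 359)
})

test_that("half-prominence extents cover the peak and stay disjoint", {
  v <- dnorm(circ_dist_deg(0:359, 50), 0, 8) +
    0.6 * dnorm(circ_dist_deg(0:359, 80), 0, 8)
  rep_ <- find_two_peaks(v)
  expect_equal(rep_$angle_deg, c(50, 80))
  ext1 <- earmap:::extent_angles(rep_$lo_deg[1], rep_$hi_deg[1])
  ext2 <- earmap:::extent_angles(rep_$lo_deg[2], rep_$hi_deg[2])
  expect_true(50 %in% ext1 && 80 %in% ext2)
  expect_length(intersect(ext1, ext2), 0)
  expect_equal(rep_$width_deg, c(length(ext1), length(ext2)))
})

test_that("localization error is the summed circular distance to nearest peaks", {
  mk_report <- function(angles) {
    v <- rep(1e-3, 360)
    for (a in angles) v <- v + dnorm(circ_dist_deg(0:359, a), 0, 3)
    find_two_peaks(v)
  }
  expect_equal(localization_error(mk_report(c(0, 11)), c(0, 11)), 0)
  expect_equal(localization_error(mk_report(c(1, 13)), c(0, 11)), 3)
  expect_equal(localization_error(mk_report(5), 350), 15)     # wraparound
  # invariance under global rotation of truth and peaks
  expect_equal(localization_error(mk_report(c(100, 111)), c(100, 111)),
               localization_error(mk_report(c(0, 11)), c(0, 11)))
  empty <- find_two_peaks(rep(1, 360))
  expect_true(is.na(localization_error(empty, 0)))
})

test_that("peak finding on analytic low-frequency profiles recovers the source", {
  # Eq-1 oracle: 300 Hz beam response resampled onto the degree grid
  for (psi in c(0, 20, -35)) {
    beams <- make_beam_set(default_geom)
    ego <- make_ego_map(matrix(analytic_response(300, psi,
                                                 beams$angles_deg,
                                                 default_geom), 1, 41))
    ev <- normalize_bands(reflect_and_resample(ego))
    m <- bayes_update(allo_map_init(1), ev)
    rep_ <- find_two_peaks(collapse_spatial(m))
    best <- min(circ_dist_deg(psi %% 360, rep_$angle_deg))
    expect_lte(best, 1, label = sprintf("psi = %g", psi))
  }
})

test_that("spectral correlation recovers constructed difference spectra", {
  nb <- 50
  m <- allo_map_init(seq(100, 5000, length.out = nb))
  # band-dependent mass split between peaks at 0 and 45
  w <- seq(0, 1, length.out = nb)                  # fraction at 45
  r0 <- dnorm(circ_dist_deg(0:359, 0), 0, 3)
  r45 <- dnorm(circ_dist_deg(0:359, 45), 0, 3)
  m$pdf <- outer(1 - w, r0 / sum(r0)) + outer(w, r45 / sum(r45))
  m$pdf <- m$pdf / rowSums(m$pdf)
  rep_ <- find_two_peaks(collapse_spatial(m))
  targets <- cbind(1 - w, w)                       # matching references
  expect_equal(spectral_correlation(m, rep_, targets,
                                    target_azimuths = c(0, 45)), 1,
               tolerance = 1e-6)
  # negated reference difference -> correlation -1
  expect_equal(spectral_correlation(m, rep_, targets[, 2:1],
                                    target_azimuths = c(0, 45)), -1,
               tolerance = 1e-6)
  # invariant to a common rescaling of the reference spectra
  expect_equal(spectral_correlation(m, rep_, targets * 1.7,
                                    target_azimuths = c(0, 45)),
               spectral_correlation(m, rep_, targets,
                                    target_azimuths = c(0, 45)))
  # fewer than two peaks -> NA sentinel
  single <- find_two_peaks(r0)
  expect_true(is.na(spectral_correlation(m, single[1, ], targets)))
})

test_that("reference spectra reflect each source's band content", {
  sc <- scene_spec(list(noise_source(0), tone_source(2400, 22)),
                   duration_frames = 4, seed = 1)
  ref <- reference_spectra(sc, default_geom, default_fb, n_frames = 2)
  expect_equal(dim(ref), c(50L, 2L))
  # the tone's spectrum concentrates at its band; noise is spread
  expect_equal(default_fb$band_centres_hz[which.max(ref[, 2])], 2400)
  expect_gt(max(ref[, 2]) / mean(ref[, 2]), 5)
  expect_lt(max(ref[, 1]) / mean(ref[, 1]), 3)
})
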