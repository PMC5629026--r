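test_that("reflection and resampling mirror the front hemifield exactly", {
  # constant energy -> constant everywhere
  ev <- reflect_and_resample(make_ego_map(matrix(1, 1, 41)))
  expect_equal(max(ev$pdf) / min(ev$pdf), 1, tolerance = 1e-9)
  # energy on the centre beam -> maxima at 0 and its back image 180
  e <- matrix(1e-3, 1, 41); e[1, 21] <- 1          # beam 21 = 0 deg
  ev <- reflect_and_resample(make_ego_map(e))
  ord <- order(-ev$pdf[1, ])[1:2]
  expect_setequal(ord - 1, c(0, 180))
  # energy on the beam nearest +30 deg -> maxima at ~30 and ~150
  beams <- make_beam_set(default_geom)
  b30 <- which.min(abs(beams$angles_deg - 30))
  e <- matrix(1e-3, 1, 41); e[1, b30] <- 1
  ev <- reflect_and_resample(make_ego_map(e))
  ord <- sort(order(-ev$pdf[1, ])[1:2]) - 1
  expect_lte(abs(ord[1] - 30), 2)
  expect_lte(abs(ord[2] - 150), 2)
  # exact front/back mirror symmetry at every angle
  a <- 0:359
  mirror <- (180 - a) %% 360
  expect_equal(ev$pdf[1, a + 1], ev$pdf[1, mirror + 1])
  # too few beams
  tiny <- make_ego_map(matrix(1, 1, 41))
  tiny$energy <- tiny$energy[, 1:3, drop = FALSE]
  tiny$beam_angles_deg <- tiny$beam_angles_deg[1:3]
  expect_error(reflect_and_resample(tiny), "at least 4 beams")
})

test_that("band normalisation yields probability rows", {
  m <- matrix(runif(5 * 360), 5, 360)
  m[3, ] <- 0                                     # degenerate row
  ev <- normalize_bands(m)
  expect_true(ev$normalized)
  expect_equal(rowSums(ev$pdf), rep(1, 5), tolerance = 1e-12)
  expect_equal(ev$pdf[3, ], rep(1 / 360, 360))
  u <- normalize_bands(matrix(1, 1, 360))
  expect_equal(u$pdf[1, ], rep(1 / 360, 360))
})

test_that("allocentric rotation is an exact mass-preserving circular shift", {
  ev <- spike_evidence(c(30, 150))
  expect_equal(rotate_to_allocentric(ev, 0)$pdf, ev$pdf)
  back <- rotate_to_allocentric(rotate_to_allocentric(ev, 35), -35)
  expect_equal(back$pdf, ev$pdf)
  # peak at egocentric 30 with head at 20 lands at allocentric 50
  rot <- rotate_to_allocentric(spike_evidence(30), 20)
  expect_equal(which.max(rot$pdf[1, ]) - 1, 50)
  expect_equal(rowSums(rot$pdf), rowSums(ev$pdf))
})

test_that("rotation agrees with the simulator's geometry end to end", {
  # a quiet source at allocentric 50 observed with head at 20 must map
  # back to 50 after reflection, normalisation and rotation
  sc <- scene_spec(list(tone_source(900, 50)), background_noise_level = 0,
                   duration_frames = 2, seed = 3)
  fr <- render_frame(sc, default_geom, 20, 0)
  bs <- epsp_transform(gammatone_filter(fr$samples, default_fb, 48000))
  ego <- ego_map_from_bands(bs, make_beam_set(default_geom), 4096, 20)
  ev <- rotate_to_allocentric(normalize_bands(reflect_and_resample(ego)))
  j <- which.min(abs(default_fb$band_centres_hz - 900))
  peak <- which.max(ev$pdf[j, ]) - 1
  expect_lte(circ_dist_deg(peak, 50), 4)
})

test_that("Bayes updates obey the conjugacy identities", {
  prior <- allo_map_init(1:3)
  ev <- spike_evidence(c(40, 140), n_bands = 3)
  post <- bayes_update(prior, ev)
  expect_equal(post$pdf, ev$pdf, tolerance = 1e-9)    # flat prior
  expect_equal(post$n_updates, 1L)
  flat_ev <- normalize_bands(matrix(1, 3, 360))
  expect_equal(bayes_update(post, flat_ev)$pdf, post$pdf,
               tolerance = 1e-12)                     # uninformative evidence
  wrong <- spike_evidence(10, n_bands = 2)
  expect_error(bayes_update(prior, wrong), "incompatible")
})

test_that("two rotations disambiguate a mirrored peak pair", {
  # head 0: images at {30, 150}; head 20: ego images {10, 170} -> allo
  # {30, 190}; the product must keep only 30
  prior <- allo_map_init(1)
  post <- bayes_update(prior, spike_evidence(c(30, 150)))
  ev2 <- rotate_to_allocentric(spike_evidence(c(10, 170)), 20)
  post <- bayes_update(post, ev2)
  expect_equal(which.max(post$pdf[1, ]) - 1, 30)
  expect_lt(post$pdf[1, 151] / post$pdf[1, 31], 1e-3)
  expect_lt(post$pdf[1, 191] / post$pdf[1, 31], 1e-3)
})

test_that("row conservation holds after every update of a real scan", {
  res <- cached("scan_tone40", {
    sc <- scene_spec(list(tone_source(2000, 40)),
                     background_noise_level = 0.05,
                     duration_frames = 8, seed = 9)
    run_scan(sc, default_geom, default_fb, schedule = c(0, 20, 40, 60),
             frames_per_pose = 2, keep_evidence = TRUE)
  })
  for (snap in res$snapshots)
    expect_equal(rowSums(snap$pdf), rep(1, 50), tolerance = 1e-9)
  expect_true(all(res$final$pdf > 0))
  expect_equal(res$final$n_updates, 8L)       # 4 poses x 2 frames
})

test_that("evidence order does not change the fused map", {
  evs <- list(spike_evidence(c(30, 150)),
              rotate_to_allocentric(spike_evidence(c(10, 170)), 20),
              rotate_to_allocentric(spike_evidence(c(350, 190)), 40))
  fuse <- function(ord) {
    m <- allo_map_init(1)
    for (i in ord) m <- bayes_update(m, evs[[i]])
    m$pdf
  }
  expect_equal(fuse(1:3), fuse(c(3, 1, 2)), tolerance = 1e-9)
  expect_equal(fuse(1:3), fuse(3:1), tolerance = 1e-9)
})

test_that("a single pose leaves the front/back ambiguity unresolved", {
  sc <- scene_spec(list(tone_source(2000, 0)), background_noise_level = 0.05,
                   duration_frames = 2, seed = 4)
  scan <- run_scan(sc, default_geom, default_fb, schedule = 0,
                   frames_per_pose = 2)
  j <- which.min(abs(default_fb$band_centres_hz - 2000))
  row <- scan$final$pdf[j, ]
  # mirrored mass at 180 comparable to the true peak at 0
  expect_gt(angle_mass(row, 180, 5) / angle_mass(row, 0, 5), 0.5)
})

test_that("an empty scene fuses to the uniform map", {
  sc <- scene_spec(list(), background_noise_level = 0.1,
                   duration_frames = 4, seed = 6)
  scan <- run_scan(sc, default_geom, default_fb, schedule = c(0, 20),
                   frames_per_pose = 2)
  # background noise is interaurally uncorrelated: no angle is favoured
  expect_lt(diff(range(scan$final$pdf)) / mean(scan$final$pdf), 1.0)
  expect_equal(rowSums(scan$final$pdf), rep(1, 50), tolerance = 1e-9)
})
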