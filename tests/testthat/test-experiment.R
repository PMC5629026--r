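tiny_config <- function(..., seed = 1) {
  experiment_config(
    sources = list(tone_source(2000, 30)),
    schedule = c(0, 40), frames_per_pose = 2,
    background_noise_level = 0.05, seed = seed, ...)
}

test_that("shipped YAML configs parse into full experiment configurations", {
  path <- system.file("configs", "fig4.yaml", package = "earmap")
  cfg <- read_experiment_config(path)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$geometry$mic_spacing_m, 0.145)
  expect_equal(cfg$schedule, seq(0L, 180L, 20L))
  expect_equal(cfg$frames_per_pose, 12L)
  expect_length(cfg$sources, 2)
  expect_equal(cfg$sources[[2]]$params$freqs_hz, 2400)
  expect_equal(cfg$sources[[2]]$azimuth_deg, 11)
  cfg7 <- read_experiment_config(system.file("configs", "fig7.yaml",
                                             package = "earmap"))
  expect_equal(vapply(cfg7$sources, `[[`, numeric(1), "azimuth_deg"),
               c(0, 45))
  expect_length(cfg7$sources[[1]]$params$freqs_hz, 8)
})

test_that("identical config and seed give bit-identical runs", {
  r1 <- run_experiment(tiny_config())
  r2 <- run_experiment(tiny_config())
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$final_map$pdf, r2$final_map$pdf)
  r3 <- run_experiment(tiny_config(seed = 2))
  expect_false(identical(r1$final_map$pdf, r3$final_map$pdf))
})

test_that("run_experiment writes outputs and a sidecar that reproduces the run", {
  out <- withr::local_tempdir()
  cfg <- tiny_config(output_dir = out)
  res <- run_experiment(cfg)
  expect_true(file.exists(file.path(out, "metrics.tsv")))
  expect_true(file.exists(file.path(out, "allo_map_final.tsv")))
  expect_true(file.exists(file.path(out, "allo_map_rot00.tsv")))
  side <- file.path(out, "run_sidecar.yaml")
  expect_true(file.exists(side))
  cfg2 <- read_experiment_config(side)
  res2 <- run_experiment(cfg2)
  expect_equal(res2$metrics, res$metrics)
  # the written final map matches the in-memory one
  tab <- read.delim(file.path(out, "allo_map_final.tsv"))
  expect_equal(unname(as.matrix(tab[, -1])), unname(res$final_map$pdf),
               tolerance = 1e-6)
})

test_that("a quiet single-tone experiment localizes the source", {
  res <- run_experiment(tiny_config())
  final_err <- min(circ_dist_deg(30, res$peaks$angle_deg))
  expect_lte(final_err, 3)
  expect_equal(nrow(res$metrics), 2L)
  expect_true(all(is.na(res$metrics$spectral_correlation)))  # one source
})

test_that("an empty scene yields a flat map and undefined metrics", {
  cfg <- experiment_config(list(), schedule = c(0, 40), frames_per_pose = 2,
                           background_noise_level = 0.1, seed = 3)
  res <- run_experiment(cfg)
  expect_true(all(is.na(res$metrics$localization_error_deg)) ||
                all(res$metrics$localization_error_deg >= 0))
  expect_lt(diff(range(res$final_map$pdf)) / mean(res$final_map$pdf), 1)
})

test_that("the command-line interface runs an experiment from a config file", {
  out <- withr::local_tempdir()
  cfg_path <- file.path(out, "cfg.yaml")
  yaml::write_yaml(list(
    schedule = list(from = 0, to = 40, by = 40),
    frames_per_pose = 2, background_noise_level = 0.05, seed = 1,
    sources = list(list(kind = "tone", azimuth_deg = 30, freq_hz = 2000))),
    cfg_path)
  status <- suppressMessages(
    earmap_main(c("run", "--config", cfg_path, "--out",
                  file.path(out, "res"))))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "res", "metrics.tsv")))
  # simulate subcommand renders a stereo WAV
  wav_path <- file.path(out, "scene.wav")
  status2 <- earmap_main(c("simulate", "--config", cfg_path,
                           "--wav", wav_path, "--head", "10"))
  expect_equal(status2, 0L)
  y <- read_wav_mono(wav_path)
  expect_equal(attr(y, "sample_rate_hz"), 48000)
  expect_gt(length(y), 4 * 4096 - 1)
  # bad invocation reports usage, non-zero status
  expect_output(expect_equal(earmap_main(character()), 1L), "usage")
})

test_that("tone_sweep tabulates resolution across frequency and separation", {
  cfg <- experiment_config(list(), schedule = seq(0, 80, 20),
                           frames_per_pose = 2,
                           background_noise_level = 0.05, seed = 1)
  tab <- tone_sweep(cfg, frequencies_hz = 2400, separations_deg = 40)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$freq_hz, 2400)
  expect_equal(tab$separation_deg, 40)
  expect_true(tab$resolved)
  expect_lte(tab$tone_error_deg, 5)
})
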