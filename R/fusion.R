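# Allocentric fusion: egocentric beam-energy images are reflected across
# the interaural axis (front/back information is redundant for a
# two-microphone array), spline-resampled onto a 1-degree grid, normalized
# per band, rotated into world coordinates by the head orientation, and
# fused across rotations by a recursive multiplicative (Bayesian) update.

.EPS_FLOOR <- 1e-12

#' Initialise an empty allocentric map
#'
#' The flat state of knowledge: every band row uniform over the 360
#' one-degree world angles (the normalized form of an all-ones
#' initialisation).
#'
#' @param band_centres_hz per-band centre frequencies.
#' @return an object of class `allo_map`: list with `pdf`
#'   (`n_bands x 360`, rows summing to 1), `band_centres_hz`, `angles_deg`
#'   (`0:359`), `n_updates`.
#' @export
allo_map_init <- function(band_centres_hz) {
  nb <- length(band_centres_hz)
  structure(
    list(pdf = matrix(1 / 360, nrow = nb, ncol = 360),
         band_centres_hz = band_centres_hz,
         angles_deg = 0:359,
         n_updates = 0L),
    class = "allo_map")
}

#' @export
print.allo_map <- function(x, ...) {
  cat(sprintf("<allo_map> %d bands x 360 deg, %d update(s)\n",
              nrow(x$pdf), x$n_updates))
  invisible(x)
}

#' Reflect an egocentric map and resample it onto the 1-degree circle
#'
#' Beam angles of a delay-and-sum array are non-uniform (peripheral beams
#' are wider than midline beams), so each band's beam energies are
#' interpolated by a cubic spline from the beam-angle grid onto whole
#' degrees in `[-90, 90]`; the back half-circle is then filled by mirror
#' reflection across the interaural axis (the value at `180 - a` equals
#' the value at `a`), which realises the front/back ambiguity of a
#' two-sensor array. Negative interpolation artifacts are clipped to a
#' small positive epsilon.
#'
#' @param ego an `ego_map`.
#' @return an object of class `ego_evidence` with an *unnormalised* `pdf`
#'   (`n_bands x 360`, world-grid order `0:359` in the egocentric frame)
#'   plus `band_centres_hz`, `head_orientation_deg`, `normalized = FALSE`.
#' @export
reflect_and_resample <- function(ego) {
  stopifnot(inherits(ego, "ego_map"))
  ang <- ego$beam_angles_deg
  if (length(ang) < 4)
    stop("interpolation unsupported: need at least 4 beams")
  nb <- nrow(ego$energy)
  front_grid <- -90:90
  grid_angles <- 0:359
  # egocentric angle of each grid point, folded to the front hemifield
  theta <- ((grid_angles + 180) %% 360) - 180          # (-180, 180]
  is_front <- abs(theta) <= 90
  theta_f <- ifelse(is_front, theta, 180 - theta)      # mirror across axis
  theta_f <- ((theta_f + 180) %% 360) - 180
  col_of <- match(round(theta_f), front_grid)
  # natural cubic spline interpolation is linear in the data, so the
  # beam-grid -> degree-grid map is one cached matrix product
  SM <- spline_operator(ang, front_grid)
  front <- ego$energy %*% t(SM)                        # nb x 181
  eps <- .EPS_FLOOR * pmax(apply(front, 1, max), 1)
  front <- pmax(front, eps)                            # column-recycled floor
  pdf <- front[, col_of, drop = FALSE]
  structure(
    list(pdf = pdf, band_centres_hz = ego$band_centres_hz,
         head_orientation_deg = ego$head_orientation_deg,
         angles_deg = grid_angles, normalized = FALSE),
    class = "ego_evidence")
}

# 181 x n_beams matrix applying natural-spline interpolation from the
# beam angles onto whole degrees -90..90; cached per beam-angle vector
spline_operator <- function(ang, front_grid) {
  key <- paste0("spl_", paste(signif(ang, 10), collapse = ","))
  cached <- .earmap_cache[[key]]
  if (!is.null(cached)) return(cached)
  SM <- vapply(seq_along(ang), function(b) {
    e <- numeric(length(ang))
    e[b] <- 1
    stats::spline(ang, e, xout = front_grid, method = "natural")$y
  }, numeric(length(front_grid)))
  .earmap_cache[[key]] <- SM
  SM
}

#' Normalise evidence within each frequency band
#'
#' Divides each band row by its sum so that the angles within any single
#' band sum to one - the competitive, winner-take-all step that lets one
#' spatial location dominate a band. Rows with no positive mass are
#' replaced by the uniform distribution.
#'
#' @param evidence an `ego_evidence` (or a bare `n_bands x 360` matrix).
#' @return an `ego_evidence` with `normalized = TRUE`.
#' @export
normalize_bands <- function(evidence) {
  if (is.matrix(evidence)) {
    evidence <- structure(
      list(pdf = evidence, band_centres_hz = NULL,
           head_orientation_deg = 0, angles_deg = 0:359,
           normalized = FALSE),
      class = "ego_evidence")
  }
  stopifnot(inherits(evidence, "ego_evidence"))
  p <- evidence$pdf
  stopifnot(all(p >= 0))
  rs <- rowSums(p)
  flat <- rs <= 0
  p[flat, ] <- 1
  rs[flat] <- ncol(p)
  evidence$pdf <- p / rs
  evidence$normalized <- TRUE
  evidence
}

#' @export
print.ego_evidence <- function(x, ...) {
  cat(sprintf("<ego_evidence> %d bands x 360 deg, head at %g deg%s\n",
              nrow(x$pdf), x$head_orientation_deg,
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Rotate egocentric evidence into world coordinates
#'
#' A circular shift of each band row by the head orientation: the value at
#' world angle `w` is the egocentric value at `w - head`. No mass is
#' created or destroyed (row sums are unchanged exactly). Head
#' orientations off the 1-degree grid are rounded to the nearest degree.
#'
#' @param evidence an `ego_evidence`.
#' @param head_orientation_deg head orientation in degrees; defaults to
#'   the orientation recorded on the evidence.
#' @return the rotated `ego_evidence` (now in the allocentric frame,
#'   `head_orientation_deg` reset to 0).
#' @export
rotate_to_allocentric <- function(evidence,
                                  head_orientation_deg = NULL) {
  stopifnot(inherits(evidence, "ego_evidence"))
  if (is.null(head_orientation_deg))
    head_orientation_deg <- evidence$head_orientation_deg
  h <- as.integer(round(head_orientation_deg)) %% 360L
  src <- ((0:359 - h) %% 360L) + 1L
  evidence$pdf <- evidence$pdf[, src, drop = FALSE]
  evidence$head_orientation_deg <- 0
  evidence
}

#' Recursive Bayesian update of the allocentric map
#'
#' Multiplies the prior map with the incoming evidence, band by band and
#' angle by angle, then renormalises each band row (the running product of
#' the raw recursion underflows numerically; per-step renormalisation
#' changes neither the per-band argmax nor peak shape ratios). Entries are
#' floored at `1e-12` before renormalisation so a single zero can never
#' permanently veto an angle.
#'
#' @param prior an `allo_map`.
#' @param evidence a normalised, allocentric-frame `ego_evidence`.
#' @return the posterior `allo_map` (update counter incremented).
#' @export
bayes_update <- function(prior, evidence) {
  stopifnot(inherits(prior, "allo_map"), inherits(evidence, "ego_evidence"))
  if (!identical(dim(prior$pdf), dim(evidence$pdf)))
    stop("incompatible maps: prior is ", nrow(prior$pdf), "x",
         ncol(prior$pdf), ", evidence is ", nrow(evidence$pdf), "x",
         ncol(evidence$pdf))
  post <- prior$pdf * evidence$pdf
  post <- pmax(post, .EPS_FLOOR)
  prior$pdf <- post / rowSums(post)
  prior$n_updates <- prior$n_updates + 1L
  prior
}

#' Run a full rotational scan of a scene
#'
#' Executes the whole pipeline for each head pose in `schedule`: render
#' `frames_per_pose` consecutive frames (with a lead-in context so the
#' filters are settled), gammatone-filter, EPSP-transform, beamform, turn
#' the beam energies into egocentric evidence
#' (reflect/resample/normalise), rotate it into world coordinates, and
#' fuse it into the allocentric map. Poses consume consecutive stretches
#' of the scene's timeline, so source waveforms are phase-continuous
#' across rotations.
#'
#' With `frame_fusion = "multiply"` (the default) every frame's evidence
#' map enters the recursive update individually, mirroring a real-time
#' system that updates the map with each incoming buffer; the per-band
#' posterior sharpens with every frame, which is what lets many
#' narrowly-separated sources resolve. With `"average"` the per-frame
#' energy maps are averaged into a single evidence image per pose and only
#' one update is applied per pose (less sharpening, one update per
#' rotation).
#'
#' @param scene a [scene_spec()] with
#'   `duration_frames >= length(schedule) * frames_per_pose`.
#' @param geometry an [array_geometry()].
#' @param filterbank a [filterbank_spec()].
#' @param schedule head orientations in degrees, one per pose (default the
#'   canonical linear scan `0, 20, ..., 180`: 10 poses, 9 rotations).
#' @param frames_per_pose frames fused into each pose.
#' @param epsp_width_ms EPSP pulse width (total support), ms.
#' @param frame_fusion `"multiply"` or `"average"` (see Details).
#' @param keep_evidence also return each pose's (last) allocentric-frame
#'   evidence.
#' @return list with `final` (the `allo_map` after the last pose),
#'   `snapshots` (list of `allo_map`s, one after each pose; element `r + 1`
#'   is the state after `r` rotations), `schedule`, and optionally
#'   `evidence`.
#' @export
run_scan <- function(scene, geometry, filterbank,
                     schedule = seq(0, 180, by = 20),
                     frames_per_pose = 12, epsp_width_ms = 1,
                     frame_fusion = c("multiply", "average"),
                     keep_evidence = FALSE) {
  stopifnot(inherits(scene, "scene_spec"),
            inherits(geometry, "array_geometry"),
            inherits(filterbank, "filterbank_spec"),
            length(schedule) >= 1, frames_per_pose >= 1)
  frame_fusion <- match.arg(frame_fusion)
  n_poses <- length(schedule)
  N <- scene$frame_length
  if (scene$duration_frames < n_poses * frames_per_pose)
    stop("scene too short: needs at least ", n_poses * frames_per_pose,
         " frames")
  beams <- make_beam_set(geometry)
  context <- 4096L                       # filter lead-in, discarded
  map <- allo_map_init(filterbank$band_centres_hz)
  snapshots <- vector("list", n_poses)
  evidence_list <- if (keep_evidence) vector("list", n_poses) else NULL
  for (p in seq_len(n_poses)) {
    k0 <- (p - 1L) * frames_per_pose * N - context
    n <- context + frames_per_pose * N
    block <- render_block(scene, geometry, schedule[p], k0, n)
    bs <- gammatone_filter(block, filterbank, geometry$sample_rate_hz)
    bs <- epsp_transform(bs, epsp_width_ms)
    bs$values <- bs$values[, , (context + 1L):n, drop = FALSE]
    if (frame_fusion == "average") {
      ego <- ego_map_from_bands(bs, beams, N, schedule[p])
      ev <- rotate_to_allocentric(normalize_bands(reflect_and_resample(ego)))
      map <- bayes_update(map, ev)
    } else {
      S <- block_energy_frames(bs, beams, N)
      for (fr in seq_len(frames_per_pose)) {
        ego <- new_ego_map(S[, , fr], beams, filterbank$band_centres_hz,
                           schedule[p], N)
        ev <- rotate_to_allocentric(normalize_bands(reflect_and_resample(ego)))
        map <- bayes_update(map, ev)
      }
    }
    snapshots[[p]] <- map
    if (keep_evidence) evidence_list[[p]] <- ev
  }
  out <- list(final = map, snapshots = snapshots, schedule = schedule)
  if (keep_evidence) out$evidence <- evidence_list
  out
}

#' Export an allocentric map as a delimited table
#'
#' @param map an `allo_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_allo_map <- function(map, path) {
  stopifnot(inherits(map, "allo_map"))
  df <- data.frame(band_hz = map$band_centres_hz, map$pdf,
                   check.names = FALSE)
  names(df) <- c("band_hz", sprintf("deg_%d", 0:359))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Image plot of an allocentric spectral-spatial map
#'
#' @param x an `allo_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.allo_map <- function(x, ...) {
  graphics::image(x = 0:359, y = x$band_centres_hz, z = t(x$pdf),
                  xlab = "allocentric azimuth (deg)",
                  ylab = "band centre (Hz)", ...)
}
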