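#' Collapse an allocentric map across frequency
#'
#' Per-angle mean of the band rows. Because every band row is a normalised
#' probability distribution, the mean is a balanced vote across bands
#' (sum and mean give identical peak structure).
#'
#' @param map an `allo_map`.
#' @return an object of class `spatial_profile`: numeric 360-vector of
#'   values with `angles_deg` attribute, circular (index 360 adjacent to
#'   index 1).
#' @export
collapse_spatial <- function(map) {
  stopifnot(inherits(map, "allo_map"))
  structure(colMeans(map$pdf), angles_deg = 0:359,
            class = "spatial_profile")
}

# circular topographic prominence of each local maximum of v
circular_peaks <- function(v) {
  n <- length(v)
  prev <- v[c(n, seq_len(n - 1))]
  nxt <- v[c(seq.int(2, n), 1)]
  cand <- which(v > prev & v >= nxt)
  if (!length(cand)) return(data.frame(idx = integer(), height = numeric(),
                                       prominence = numeric()))
  prom <- vapply(cand, function(i) {
    h <- v[i]
    walk <- function(step) {
      m <- h
      j <- i
      for (k in seq_len(n - 1)) {
        j <- ((j - 1 + step) %% n) + 1
        if (v[j] > h) return(m)
        if (v[j] < m) m <- v[j]
      }
      NA_real_                      # no higher ground: global maximum side
    }
    lo_l <- walk(-1L)
    lo_r <- walk(+1L)
    if (is.na(lo_l) || is.na(lo_r)) h - min(v)      # global max
    else h - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(idx = cand, height = v[cand], prominence = prom)
}

#' Find the two most prominent peaks of a spatial profile
#'
#' Local maxima of the circular profile are ranked by topographic
#' prominence (for the global maximum, prominence is height above the
#' global minimum) and the top `max_peaks` are reported together with
#' their half-prominence angular extents - the contiguous arc around each
#' peak where the profile stays above `height - prominence / 2`, truncated
#' at the circular midpoint towards the other reported peak so extents
#' never overlap. Ties in prominence are broken by the smaller angle.
#'
#' @param profile a `spatial_profile` (or bare 360-vector).
#' @param max_peaks number of peaks to report.
#' @return an object of class `peak_report`: data frame with columns
#'   `angle_deg`, `height`, `prominence`, `lo_deg`, `hi_deg` (extent
#'   endpoints, inclusive, possibly wrapping), `width_deg`. A constant
#'   profile yields an empty report with attribute `flat = TRUE`.
#' @export
find_two_peaks <- function(profile, max_peaks = 2) {
  v <- as.numeric(profile)
  n <- length(v)
  empty <- data.frame(angle_deg = numeric(), height = numeric(),
                      prominence = numeric(), lo_deg = numeric(),
                      hi_deg = numeric(), width_deg = numeric())
  if (diff(range(v)) == 0) {
    attr(empty, "flat") <- TRUE
    class(empty) <- c("peak_report", "data.frame")
    return(empty)
  }
  pk <- circular_peaks(v)
  pk <- pk[order(-pk$prominence, pk$idx), , drop = FALSE]
  pk <- pk[seq_len(min(max_peaks, nrow(pk))), , drop = FALSE]
  angles <- pk$idx - 1L

  # half-prominence extents, truncated at the midpoint towards the other peak
  res <- lapply(seq_len(nrow(pk)), function(r) {
    i <- pk$idx[r]
    level <- pk$height[r] - pk$prominence[r] / 2
    max_span <- floor((n - 1) / 2)
    if (nrow(pk) > 1) {
      other <- pk$idx[-r]
      gap <- min(circ_dist_deg(angles[r], other - 1L))
      max_span <- min(max_span, max(1, floor(gap / 2)))
    }
    lo <- hi <- i
    for (k in seq_len(max_span)) {
      j <- ((i - 1 - k) %% n) + 1
      if (v[j] < level) break
      lo <- j
    }
    for (k in seq_len(max_span)) {
      j <- ((i - 1 + k) %% n) + 1
      if (v[j] < level) break
      hi <- j
    }
    width <- ((hi - lo) %% n) + 1
    c(lo = lo - 1L, hi = hi - 1L, width = width)
  })
  res <- do.call(rbind, res)
  out <- data.frame(angle_deg = angles, height = pk$height,
                    prominence = pk$prominence,
                    lo_deg = res[, "lo"], hi_deg = res[, "hi"],
                    width_deg = res[, "width"])
  class(out) <- c("peak_report", "data.frame")
  out
}

# angles (0-based grid) covered by a peak's extent, wrapping included
extent_angles <- function(lo, hi, n = 360) {
  if (hi >= lo) lo:hi else c(lo:(n - 1), 0:hi)
}

#' Total localization error of a peak report
#'
#' Sum over true source azimuths of the circular angular distance to the
#' nearest reported peak.
#'
#' @param report a `peak_report`.
#' @param truth numeric vector of true source azimuths, degrees.
#' @return error in degrees, or `NA` if the report is empty.
#' @export
localization_error <- function(report, truth) {
  stopifnot(inherits(report, "peak_report"))
  if (nrow(report) == 0) return(NA_real_)
  sum(vapply(truth, function(a)
    min(circ_dist_deg(a, report$angle_deg)), numeric(1)))
}

#' Reference spectra of the scene's sources
#'
#' Per-band average power of each source's clean (unmixed, undelayed)
#' waveform through the same gammatone filter bank the analyzer uses -
#' the ground-truth spectra that [spectral_correlation()] compares
#' against.
#'
#' @param scene a [scene_spec()].
#' @param geometry an [array_geometry()].
#' @param filterbank a [filterbank_spec()].
#' @param n_frames number of frames of signal to average over.
#' @return `n_bands x n_sources` matrix of band RMS values.
#' @export
reference_spectra <- function(scene, geometry, filterbank, n_frames = 4) {
  stopifnot(length(scene$sources) >= 1)
  N <- scene$frame_length
  context <- 4096L
  n <- context + n_frames * N
  out <- matrix(0, filterbank$n_bands, length(scene$sources))
  for (i in seq_along(scene$sources)) {
    x <- source_channel(scene, geometry, i, k0 = -context, n = n,
                        delay_s = 0)
    bs <- gammatone_filter(rbind(x, x), filterbank,
                           geometry$sample_rate_hz)
    seg <- bs$values[, 1, (context + 1L):n]
    out[, i] <- sqrt(rowMeans(seg^2))
  }
  out
}

#' Spectral correlation between resolved and true sources
#'
#' For each of the two reported peaks, the map probability is summed over
#' the peak's half-prominence angular extent in every band, giving an
#' estimated "spectrum" per peak (probability mass, analogous to - not
#' equal to - physical power). The Pearson correlation between the
#' difference of the two estimated spectra and the difference of the two
#' reference spectra measures how well the scene was unmixed in
#' frequency.
#'
#' Peaks are matched to reference columns by proximity to
#' `target_azimuths` when given; otherwise peak 1 pairs with reference
#' column 1.
#'
#' @param map an `allo_map`.
#' @param report a `peak_report` with at least 2 peaks.
#' @param targets `n_bands x 2` matrix of reference spectra (e.g. from
#'   [reference_spectra()]).
#' @param target_azimuths optional length-2 vector of the true azimuths of
#'   the two reference sources, used to order the peaks.
#' @return Pearson correlation in `[-1, 1]`, or `NA` if fewer than 2
#'   peaks.
#' @export
spectral_correlation <- function(map, report, targets,
                                 target_azimuths = NULL) {
  stopifnot(inherits(map, "allo_map"), inherits(report, "peak_report"),
            is.matrix(targets), ncol(targets) == 2,
            nrow(targets) == nrow(map$pdf))
  if (nrow(report) < 2) return(NA_real_)
  est <- vapply(1:2, function(r) {
    cols <- extent_angles(report$lo_deg[r], report$hi_deg[r]) + 1L
    rowSums(map$pdf[, cols, drop = FALSE])
  }, numeric(nrow(map$pdf)))
  ord <- 1:2
  if (!is.null(target_azimuths)) {
    # assign each target the nearest peak
    d <- outer(target_azimuths, report$angle_deg[1:2], circ_dist_deg)
    ord <- if (which.min(d[1, ]) == 2) c(2L, 1L) else 1:2
  }
  d_est <- est[, ord[2]] - est[, ord[1]]
  d_ref <- targets[, 2] - targets[, 1]
  if (stats::sd(d_est) == 0 || stats::sd(d_ref) == 0) return(NA_real_)
  stats::cor(d_est, d_ref)
}

#' Per-rotation metrics for a completed scan
#'
#' Applies the peak / localization / spectral-correlation measures to
#' every snapshot of a [run_scan()] result.
#'
#' @param scan result of [run_scan()].
#' @param truth true source azimuths (degrees), in scene-source order.
#' @param targets optional `n_bands x 2` reference spectra for
#'   [spectral_correlation()] (only used when the scene has two sources).
#' @return data frame with one row per pose: `rotation` (0 = first pose),
#'   `head_deg`, `localization_error_deg`, `spectral_correlation`,
#'   `peak1_deg`, `peak2_deg`, `peak1_width_deg`, `peak2_width_deg`.
#' @export
scan_metrics <- function(scan, truth, targets = NULL) {
  rows <- lapply(seq_along(scan$snapshots), function(p) {
    rep_ <- find_two_peaks(collapse_spatial(scan$snapshots[[p]]))
    sc <- if (!is.null(targets) && length(truth) == 2)
      spectral_correlation(scan$snapshots[[p]], rep_, targets, truth)
    else NA_real_
    data.frame(
      rotation = p - 1L,
      head_deg = scan$schedule[p],
      localization_error_deg = localization_error(rep_, truth),
      spectral_correlation = sc,
      peak1_deg = if (nrow(rep_) >= 1) rep_$angle_deg[1] else NA_real_,
      peak2_deg = if (nrow(rep_) >= 2) rep_$angle_deg[2] else NA_real_,
      peak1_width_deg = if (nrow(rep_) >= 1) rep_$width_deg[1] else NA_real_,
      peak2_width_deg = if (nrow(rep_) >= 2) rep_$width_deg[2] else NA_real_)
  })
  do.call(rbind, rows)
}
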