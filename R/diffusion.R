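bilinear_sample <- function(frame, x, y) {
  # x, y in pixel coordinates (1-based, pixel centres at integers)
  nx <- ncol(frame); ny <- nrow(frame)
  x0 <- pmin(pmax(floor(x), 1), nx - 1); y0 <- pmin(pmax(floor(y), 1), ny - 1)
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  frame[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    frame[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    frame[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    frame[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Extract the cross-section intensity profile of one frame
#'
#' Samples the quantification line at pixel pitch (bilinear interpolation for
#' non-axis-aligned lines), averaging across the line's width perpendicular
#' to it. Positions are micrometres from the line start.
#'
#' @param series a [diffusion_series()].
#' @param frame_index which frame.
#' @return data frame: `position_um`, `intensity`.
#' @export
extract_profile <- function(series, frame_index) {
  if (frame_index < 1 || frame_index > length(series$frames))
    oc_abort("frame index out of range", "invalid_input")
  fr <- series$frames[[frame_index]]
  ln <- series$profile_line
  v <- c(ln$end[1] - ln$start[1], ln$end[2] - ln$start[2])
  len <- sqrt(sum(v^2))
  u <- v / len
  perp <- c(-u[2], u[1])
  n_s <- floor(len) + 1L
  tpos <- seq(0, len, length.out = n_s)
  w <- ln$width %||% 1L
  offs <- seq(-(w - 1) / 2, (w - 1) / 2, length.out = max(w, 1))
  acc <- 0
  for (o in offs) {
    xs <- ln$start[1] + tpos * u[1] + o * perp[1]
    ys <- ln$start[2] + tpos * u[2] + o * perp[2]
    acc <- acc + bilinear_sample(fr, xs, ys)
  }
  data.frame(position_um = tpos * series$pixel_size_um,
             intensity = acc / length(offs))
}

series_source_level <- function(series) {
  s <- series$source_level
  if (!is.na(s)) return(s)
  # fall back to the perfusion-channel region: leading 5% of the first
  # frame's quantification line
  prof <- extract_profile(series, 1L)
  n <- max(2L, ceiling(0.05 * nrow(prof)))
  mean(prof$intensity[seq_len(n)])
}

#' Normalized intensity at the chamber centre over time
#'
#' Intensity at the midpoint of the quantification line, per frame, divided
#' by the source level.
#'
#' @param series a [diffusion_series()] with >= 2 frames.
#' @return data frame: `time_min`, `normalized_intensity` (in `[0, 1]` up to
#'   noise).
#' @export
normalized_center_intensity <- function(series) {
  if (length(series$frames) < 2)
    oc_abort("need >= 2 frames", "invalid_input")
  src <- series_source_level(series)
  if (!is.finite(src) || src <= 0)
    oc_abort("source level must be > 0", "invalid_input")
  vals <- vapply(seq_along(series$frames), function(i) {
    prof <- extract_profile(series, i)
    prof$intensity[ceiling(nrow(prof) / 2)]
  }, numeric(1))
  data.frame(time_min = series$times_min, normalized_intensity = vals / src)
}

#' First sampled time at which the chamber centre saturates
#'
#' @param series a [diffusion_series()].
#' @param threshold saturation fraction of the source level, in `(0, 1]`.
#' @return first sampled time (minutes) with normalized centre intensity at
#'   or above `threshold`, or `NA` ("not reached").
#' @export
saturation_time <- function(series, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    oc_abort("`threshold` must be in (0, 1]", "invalid_input")
  ci <- normalized_center_intensity(series)
  hit <- which(ci$normalized_intensity >= threshold)
  if (length(hit) == 0) return(NA_real_)
  ci$time_min[hit[1]]
}

#' Estimate the diffusivity from a profile time series
#'
#' Joint least-squares fit of the analytic two-source transport model to the
#' chamber-interior samples of every frame. For each candidate D the source
#' amplitude enters linearly and is profiled out in closed form, leaving a
#' 1-D minimization over log10(D); the estimate is therefore invariant to
#' rescaling all intensities by a constant.
#'
#' @param series a [diffusion_series()] with >= 3 frames.
#' @param chamber_width_um chamber width W.
#' @param chamber_start_um position of the left chamber edge along the
#'   quantification line (um from the line start); defaults to the flanking
#'   channel width of the standard chip (250 um).
#' @param D_range_um2s search interval for D (um^2/s).
#' @return list: `D_um2s`, `residual` (RMS misfit in intensity units),
#'   `amplitude` (fitted source level).
#' @export
estimate_diffusivity <- function(series, chamber_width_um = 1200,
                                 chamber_start_um = 250,
                                 D_range_um2s = c(0.1, 1e4)) {
  if (length(series$frames) < 3)
    oc_abort("need >= 3 frames", "invalid_input")
  profs <- lapply(seq_along(series$frames), function(i)
    extract_profile(series, i))
  margin <- 0.02 * chamber_width_um   # keep clear of the edge pixels
  xs <- profs[[1]]$position_um - chamber_start_um
  inside <- xs > margin & xs < chamber_width_um - margin
  if (sum(inside) < 5)
    oc_abort("quantification line barely crosses the chamber",
             "invalid_input")
  y <- unlist(lapply(profs, function(p) p$intensity[inside]))
  spread <- vapply(profs, function(p) sd(p$intensity[inside]), numeric(1))
  tspan <- diff(range(vapply(profs, function(p)
    mean(p$intensity[inside]), numeric(1))))
  if (max(spread) < 1e-8 * max(abs(y), 1e-300) && tspan < 1e-8 * max(abs(y)))
    oc_abort("profiles are flat: diffusivity is not identifiable",
             "non_identifiable")
  x_um <- xs[inside]
  tsec <- series$times_min * 60
  sse <- function(log10D) {
    D <- 10^log10D
    m <- unlist(lapply(tsec, function(t_s)
      diffusion_profile_analytic(x_um, t_s, D, chamber_width_um)))
    a <- sum(m * y) / max(sum(m * m), .Machine$double.xmin)
    sum((y - a * m)^2)
  }
  opt <- optimize(sse, log10(D_range_um2s), tol = 1e-6)
  D_hat <- 10^opt$minimum
  m <- unlist(lapply(tsec, function(t_s)
    diffusion_profile_analytic(x_um, t_s, D_hat, chamber_width_um)))
  a <- sum(m * y) / sum(m * m)
  list(D_um2s = D_hat, residual = sqrt(opt$objective / length(y)),
       amplitude = a)
}
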