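erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

#' Analytic concentration profile between two constant sources
#'
#' Normalized solution of the 1-D diffusion equation on `[0, W]` with
#' constant-concentration boundaries (the two perfusion channels) and zero
#' initial interior concentration. Evaluated by superposed erfc fronts
#' (method of images) while the fronts are narrow relative to the chamber,
#' and by the Fourier sine completion of the same solution once they
#' overlap; both branches agree to machine precision where they meet.
#'
#' @param x_um position(s) across the chamber, um, in `[0, W]`.
#' @param t_s time in seconds (>= 0).
#' @param D_um2s diffusivity, um^2/s (> 0).
#' @param width_um chamber width W, um.
#' @return concentration as a fraction of the source level, in `[0, 1]`.
#' @export
diffusion_profile_analytic <- function(x_um, t_s, D_um2s, width_um) {
  if (D_um2s <= 0 || width_um <= 0)
    oc_abort("D and width must be > 0", "invalid_input")
  W <- width_um
  if (t_s <= 0)
    return(ifelse(x_um <= 0 | x_um >= W, 1, 0))
  s <- 2 * sqrt(D_um2s * t_s)
  if (s < W) {
    # method of images: the depletion v = 1 - u is a sum of image kernels
    # integrated over the chamber; each n-term decays like erfc(nW/s)
    E <- function(y) 2 * pnorm(sqrt(2) * y / s) - 1
    v <- 0
    N <- ceiling(2 * s / W) + 2
    for (n in -N:N)
      v <- v + E(x_um - 2 * n * W) -
        0.5 * E(x_um - (2 * n + 1) * W) -
        0.5 * E(x_um - (2 * n - 1) * W)
    u <- 1 - v
  } else {
    u <- 1
    k <- 1
    repeat {
      term <- (4 / (k * pi)) * sin(k * pi * x_um / W) *
        exp(-(k * pi / W)^2 * D_um2s * t_s)
      u <- u - term
      k <- k + 2
      if (exp(-(k * pi / W)^2 * D_um2s * t_s) * 4 / (k * pi) < 1e-15 ||
          k > 20001) break
    }
  }
  pmin(pmax(u, 0), 1)
}

#' Time-lapse diffusion series
#'
#' A stack of 2-D frames with times and a quantification line across the
#' chamber, the container consumed by the diffusion quantification
#' operations.
#'
#' @param frames list of 2-D matrices (y, x), one per time point.
#' @param times_min acquisition times in minutes, strictly increasing.
#' @param pixel_size_um physical pixel pitch.
#' @param profile_line list with `start`, `end` (pixel `(x, y)` pairs) and
#'   `width` (averaging width in pixels, odd); default spans the middle row.
#' @param source_level source intensity (a.u.); `NA` means "estimate from
#'   the first frame's line start" (the perfusion-channel region).
#' @return object of class `diffusion_series`.
#' @export
diffusion_series <- function(frames, times_min, pixel_size_um = 4,
                             profile_line = NULL, source_level = NA_real_) {
  if (!is.list(frames) || length(frames) != length(times_min))
    oc_abort("need one time per frame", "invalid_input")
  if (any(diff(times_min) <= 0))
    oc_abort("times must be strictly increasing", "invalid_input")
  dims <- dim(frames[[1]])
  if (is.null(profile_line))
    profile_line <- list(start = c(1, ceiling(dims[1] / 2)),
                         end = c(dims[2], ceiling(dims[1] / 2)),
                         width = 5L)
  for (p in list(profile_line$start, profile_line$end))
    if (p[1] < 1 || p[1] > dims[2] || p[2] < 1 || p[2] > dims[1])
      oc_abort("profile line endpoints outside frame bounds", "invalid_input")
  structure(list(frames = frames, times_min = as.numeric(times_min),
                 pixel_size_um = pixel_size_um, profile_line = profile_line,
                 source_level = source_level),
            class = "diffusion_series")
}

#' Generate a synthetic hydrogel diffusion series
#'
#' Renders a transverse strip of the chip: two constant-intensity perfusion
#' channels flanking a chamber whose interior follows the analytic
#' constant-source solution (see [diffusion_profile_analytic()]), sampled at
#' the stated times with optional Gaussian noise. Ground truth (D, geometry)
#' is attached as an attribute.
#'
#' @param D_um2s true diffusivity, um^2/s.
#' @param chamber_width_um chamber width (default 1200 um, the chip's
#'   compartment width).
#' @param channel_width_um flanking perfusion channel width (default 250 um).
#' @param times_min sampled times, minutes (default every 15 min for
#'   2 h 30).
#' @param pixel_size_um pixel pitch.
#' @param height_px strip height in pixels.
#' @param source_level source intensity (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param seed RNG seed (noise only).
#' @return a [diffusion_series()] with attribute `truth`.
#' @export
generate_diffusion_series <- function(D_um2s = 100, chamber_width_um = 1200,
                                      channel_width_um = 250,
                                      times_min = seq(0, 150, by = 15),
                                      pixel_size_um = 4, height_px = 40,
                                      source_level = 1, noise_sd = 0,
                                      seed = 1L) {
  if (D_um2s <= 0) oc_abort("`D_um2s` must be > 0", "invalid_input")
  if (any(diff(times_min) <= 0))
    oc_abort("times must be sorted ascending", "invalid_input")
  set.seed(seed)
  ch_px <- round(channel_width_um / pixel_size_um)
  W_px <- round(chamber_width_um / pixel_size_um)
  nx <- 2 * ch_px + W_px
  x_px <- seq_len(nx)
  # chamber coordinate of each pixel centre, um from the left chamber edge
  x_um <- (x_px - 0.5 - ch_px) * pixel_size_um
  frames <- lapply(times_min, function(tm) {
    prof <- numeric(nx)
    inside <- x_um > 0 & x_um < chamber_width_um
    prof[!inside] <- 1
    prof[inside] <- diffusion_profile_analytic(x_um[inside], tm * 60,
                                               D_um2s, chamber_width_um)
    fr <- matrix(rep(prof * source_level, each = height_px), height_px, nx)
    if (noise_sd > 0)
      fr <- pmin(pmax(fr + rnorm(length(fr), 0, noise_sd), 0), source_level)
    fr
  })
  ser <- diffusion_series(frames, times_min, pixel_size_um,
                          source_level = source_level)
  attr(ser, "truth") <- list(D_um2s = D_um2s,
                             chamber_width_um = chamber_width_um,
                             channel_width_um = channel_width_um,
                             source_level = source_level)
  ser
}

#' Write / read a diffusion series as numbered TIFF frames plus a times CSV
#'
#' @param series a [diffusion_series()].
#' @param dir output directory (created if needed); frames are written as
#'   `frame_###.tif` (16-bit) and times as `times.csv`.
#' @return `write_diffusion_series` returns `dir` invisibly;
#'   `read_diffusion_series` returns a [diffusion_series()].
#' @export
write_diffusion_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(1, vapply(series$frames, max, numeric(1)))
  for (i in seq_along(series$frames))
    tiff::writeTIFF(round(series$frames[[i]] / mx * 65535) / 65535,
                    file.path(dir, sprintf("frame_%03d.tif", i)),
                    bits.per.sample = 16L)
  write.csv(data.frame(frame = seq_along(series$times_min),
                       time_min = series$times_min,
                       intensity_scale = mx),
            file.path(dir, "times.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_diffusion_series
#' @param pixel_size_um pixel pitch of the stored frames.
#' @export
read_diffusion_series <- function(dir, pixel_size_um = 4) {
  tf <- file.path(dir, "times.csv")
  if (!file.exists(tf))
    oc_abort(sprintf("times table not found in %s", dir), "missing_file")
  times <- read.csv(tf)
  frames <- lapply(times$frame, function(i) {
    f <- file.path(dir, sprintf("frame_%03d.tif", i))
    if (!file.exists(f))
      oc_abort(sprintf("frame missing: %s", f), "missing_file")
    tiff::readTIFF(f) * times$intensity_scale[1] * 65535 / 65535
  })
  diffusion_series(frames, times$time_min, pixel_size_um)
}
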