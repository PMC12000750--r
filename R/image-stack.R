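#' Multi-channel 3D image stack
#'
#' The unit of image analysis: a 4-D intensity array indexed
#' `(channel, z, y, x)` together with the physical voxel size and a map from
#' biological channel roles to channel indices. The default voxel geometry
#' matches 20x confocal acquisition at 0.42 um per pixel with a 2 um z-step.
#'
#' @param voxels 4-D numeric array, non-negative, indexed (channel, z, y, x).
#' @param voxel_size numeric triple `(dz, dy, dx)` in micrometres, all > 0.
#' @param channel_roles named integer vector mapping roles to channel
#'   indices; allowed roles are `nuclei`, `actin`, `nascent`, `collagen1`,
#'   `collagen2`, `live`, `dead`. No two roles may share an index.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size = c(2, 0.42, 0.42), channel_roles) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    oc_abort("`voxels` must be a 4-D array (channel, z, y, x)", "invalid_input")
  if (!is.numeric(voxels))
    oc_abort("voxel data must be numeric", "nonnumeric_pixels")
  if (any(voxels < 0, na.rm = TRUE))
    oc_abort("voxel intensities must be non-negative", "invalid_input")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    oc_abort("`voxel_size` must be 3 positive numbers (dz, dy, dx) in um",
             "invalid_input")
  roles_ok <- c("nuclei", "actin", "nascent", "collagen1", "collagen2",
                "live", "dead")
  if (is.null(names(channel_roles)) || !all(names(channel_roles) %in% roles_ok))
    oc_abort(paste0("channel roles must be named from: ",
                    paste(roles_ok, collapse = ", ")), "invalid_input")
  channel_roles <- vapply(channel_roles, as.integer, integer(1))
  nc <- dim(voxels)[1]
  if (any(channel_roles < 1L) || any(channel_roles > nc))
    oc_abort(sprintf("channel index out of range 1..%d", nc),
             "channel_mismatch")
  if (anyDuplicated(channel_roles))
    oc_abort("two roles map to the same channel index", "invalid_input")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel_roles = channel_roles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s), %d x %d x %d (z,y,x) voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (dz,dy,dx): %s um\n",
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  cat(sprintf("  roles: %s\n",
              paste(names(x$channel_roles), x$channel_roles,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Volume of one voxel in cubic micrometres
#' @param stack an [image_stack()].
#' @return scalar, `dz * dy * dx`.
#' @export
voxel_volume <- function(stack) prod(stack$voxel_size)

#' Extract one channel of a stack by role
#' @param stack an [image_stack()].
#' @param role one of the declared channel roles.
#' @return 3-D array (z, y, x).
#' @export
stack_channel <- function(stack, role) {
  if (!role %in% names(stack$channel_roles))
    oc_abort(sprintf("role '%s' not present in stack", role), "missing_role")
  ch <- stack$channel_roles[[role]]
  nd <- dim(stack$voxels)
  array(stack$voxels[ch, , , ], dim = nd[2:4])
}

#' Read a multi-channel TIFF z-stack
#'
#' Pages are expected channel-interleaved within z (page = (z-1) * n_channels
#' + channel), the layout written by [write_image_stack()] and by ImageJ's
#' default XYCZT order. Intensities are preserved bit-exactly (integer TIFF
#' samples are returned as stored).
#'
#' @param path TIFF file path.
#' @param channel_roles named integer role map (see [image_stack()]); the
#'   number of channels in the file is taken as `max(channel_roles)` unless
#'   `n_channels` is given.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param n_channels declared channel count; must divide the page count.
#' @param normalize divide integer data by its bit-depth maximum to map onto
#'   `[0, 1]` (the scale used by the analysis defaults). Default `FALSE`
#'   (bit-exact).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, channel_roles,
                             voxel_size = c(2, 0.42, 0.42),
                             n_channels = max(channel_roles),
                             normalize = FALSE) {
  if (!file.exists(path))
    oc_abort(sprintf("file not found: %s", path), "missing_file")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!all(vapply(pages, is.numeric, logical(1))))
    oc_abort("TIFF contains non-numeric pixel data", "nonnumeric_pixels")
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0L)
    oc_abort(sprintf(
      "declared %d channels but file has %d pages (not divisible)",
      n_channels, n_pages), "channel_mismatch")
  nz <- n_pages %/% n_channels
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(n_channels, nz, ny, nx))
  for (z in seq_len(nz))
    for (ch in seq_len(n_channels))
      vox[ch, z, , ] <- pages[[(z - 1L) * n_channels + ch]]
  if (normalize) {
    bits <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    vox <- vox / (2^bits - 1)
  }
  image_stack(vox, voxel_size = voxel_size, channel_roles = channel_roles)
}

#' Write a stack as a multi-page TIFF
#'
#' Pages are written channel-interleaved within z. Integer-valued data in
#' `[0, 2^bits - 1]` round-trips bit-exactly through [read_image_stack()];
#' continuous data in `[0, 1]` is quantized to the requested bit depth.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 16L) {
  vox <- stack$voxels
  mx <- 2^bits - 1
  if (max(vox) > 1) {
    if (max(vox) > mx)
      oc_abort(sprintf("intensities exceed %d-bit range", bits),
               "invalid_input")
    vox <- vox / mx                      # integer data: exact under /mx * mx
  } else {
    vox <- round(vox * mx) / mx          # continuous data: quantize
  }
  d <- dim(vox)
  pages <- vector("list", d[1] * d[2])
  for (z in seq_len(d[2]))
    for (ch in seq_len(d[1]))
      pages[[(z - 1L) * d[1] + ch]] <- matrix(vox[ch, z, , ], d[3], d[4])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
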