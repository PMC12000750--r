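# Thresholding: automatic Otsu on the pooled voxel histogram (the exact
# manual-matched thresholds of the original workflow are not published), or a
# fixed numeric override from the config.
oc_threshold <- function(v, method) {
  if (is.numeric(method)) return(method)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[2])  # constant channel: nothing above
  vn <- (as.numeric(v) - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(EBImage::Image(matrix(vn, ncol = 1)),
                         range = c(0, 1), levels = 256L)
  rng[1] + as.numeric(thr01) * (rng[2] - rng[1])
}

label_volume <- function(labels, dims, voxel_size, n_objects) {
  arr <- array(as.integer(labels), dim = dims)
  attr(arr, "n_objects") <- as.integer(n_objects)
  attr(arr, "voxel_size") <- voxel_size
  class(arr) <- c("label_volume", class(arr))
  arr
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d object(s)\n",
              paste(dim(x), collapse = " x "), attr(x, "n_objects")))
  invisible(x)
}

# Relabel to a contiguous 1..K set, ordered by first (column-major) voxel.
relabel_contiguous <- function(lab) {
  ids <- unique(lab[lab > 0L])
  map <- integer(max(c(ids, 0L)) + 1L)
  map[ids + 1L] <- seq_along(ids)
  out <- lab
  pos <- lab > 0L
  out[pos] <- map[lab[pos] + 1L]
  list(labels = out, n = length(ids))
}

# (z, y, x) voxel indices of a flat index set, for dims (nz, ny, nx).
flat_to_zyx <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1]
  rest <- idx0 %/% dims[1]
  cbind(z = z + 1L, y = rest %% dims[2] + 1L, x = rest %/% dims[2] + 1L)
}

#' Segment nuclei as seeds for single-cell analysis
#'
#' Thresholds the nuclei channel (Otsu by default), labels 26-connected
#' components in 3D, removes objects below the minimum nucleus volume, and
#' splits touching nuclei by a seeded watershed on the anisotropic Euclidean
#' distance transform: distance maxima closer than `split_min_distance_um`
#' are merged into one seed, so a lone convex nucleus always yields a single
#' object. Deterministic for fixed input and configuration.
#'
#' @param stack an [image_stack()] with a `nuclei` role.
#' @param config an [analysis_config()] (threshold, min volume, split
#'   distance).
#' @return a `label_volume`: 3-D integer array, 0 = background, labels
#'   contiguous `1..K`.
#' @export
segment_nuclei <- function(stack, config = analysis_config()) {
  v <- stack_channel(stack, "nuclei")
  dims <- dim(v)
  vs <- stack$voxel_size
  thr <- oc_threshold(v, config$nuclei_threshold)
  mask <- v > thr
  if (!any(mask)) {
    oc_warn("empty nuclei segmentation: no voxels above threshold",
            "empty_segmentation")
    return(label_volume(integer(length(v)), dims, vs, 0L))
  }
  lab <- cpp_label3d(as.logical(mask), dims)
  minvox <- max(1, ceiling(config$min_nucleus_volume_um3 / prod(vs)))
  counts <- tabulate(lab[lab > 0L])
  small <- which(counts < minvox)
  if (length(small)) {
    mask[array(lab %in% small, dims)] <- FALSE
    lab[lab %in% small] <- 0L
  }
  if (!any(mask)) {
    oc_warn("empty nuclei segmentation after the volume filter",
            "empty_segmentation")
    return(label_volume(integer(length(v)), dims, vs, 0L))
  }

  edt <- cpp_edt3d(as.logical(mask), dims, vs)
  interior <- as.logical(mask) & edt >= 1
  if (!any(interior)) interior <- as.logical(mask)
  mx <- cpp_local_maxima3d(edt, interior, dims)
  midx <- which(mx)
  if (length(midx) == 0 || length(midx) > 20000L) {
    if (length(midx) > 20000L)
      oc_warn("too many distance maxima; skipping watershed splitting",
              "split_skipped")
    rl <- relabel_contiguous(array(lab, dims))
    return(label_volume(rl$labels, dims, vs, rl$n))
  }
  zyx <- flat_to_zyx(midx, dims)
  coords_um <- sweep(zyx - 0.5, 2, vs, `*`)
  # non-maximum suppression: accept peaks in decreasing depth order,
  # suppressing any peak within the minimum split distance of an accepted
  # one; ties broken by voxel order for determinism
  ord <- order(-edt[midx], midx)
  acc <- integer(0)
  for (i in ord) {
    if (length(acc) == 0 ||
        all(colSums((t(coords_um[acc, , drop = FALSE]) -
                       coords_um[i, ])^2) >
              config$split_min_distance_um^2))
      acc <- c(acc, i)
  }
  seeds <- integer(length(v))
  seeds[midx[acc]] <- seq_along(acc)
  ws <- cpp_watershed3d(max(edt) - edt, seeds, as.logical(mask), dims)
  counts <- tabulate(ws[ws > 0L])
  small <- which(counts < minvox)
  if (length(small)) ws[ws %in% small] <- 0L
  rl <- relabel_contiguous(array(ws, dims))
  label_volume(rl$labels, dims, vs, rl$n)
}

#' Centroids of labeled objects
#' @param labels a `label_volume`.
#' @return data frame: `label`, `z_um`, `y_um`, `x_um`, `voxels` (centroids
#'   at voxel-centre coordinates).
#' @export
label_centroids <- function(labels) {
  dims <- dim(labels)
  vs <- attr(labels, "voxel_size")
  idx <- which(labels > 0L)
  if (length(idx) == 0)
    return(data.frame(label = integer(), z_um = numeric(), y_um = numeric(),
                      x_um = numeric(), voxels = integer()))
  zyx <- flat_to_zyx(idx, dims)
  lb <- labels[idx]
  agg <- function(w) tapply((w - 0.5), lb, mean)
  data.frame(label = as.integer(names(agg(zyx[, 1]))),
             z_um = as.numeric(agg(zyx[, 1])) * vs[1],
             y_um = as.numeric(agg(zyx[, 2])) * vs[2],
             x_um = as.numeric(agg(zyx[, 3])) * vs[3],
             voxels = as.integer(tapply(lb, lb, length)))
}

#' Assign every foreground voxel to a seed cell
#'
#' Grows cell territories from the nucleus seeds by a seeded watershed on the
#' inverted combined actin + nascent intensity landscape, over the union of
#' the two channels' foreground masks. Assignment is then limited to each
#' seed's bounding box padded by the crop margin, mirroring the per-cell crop
#' of the original workflow; the result partitions the retained foreground
#' (each foreground voxel carries at most one label, voxels outside every
#' crop are unassigned).
#'
#' @param seeds a `label_volume` from [segment_nuclei()] with >= 1 object.
#' @param stack an [image_stack()] with `actin` and `nascent` roles.
#' @param config an [analysis_config()].
#' @return a `label_volume` of cell territories.
#' @export
assign_cell_territories <- function(seeds, stack, config = analysis_config()) {
  if (attr(seeds, "n_objects") < 1)
    oc_abort("need at least one seed", "invalid_input")
  dims <- dim(seeds)
  vs <- stack$voxel_size
  actin <- stack_channel(stack, "actin")
  nascent <- stack_channel(stack, "nascent")
  thr_a <- oc_threshold(actin, config$actin_threshold)
  thr_n <- oc_threshold(nascent, config$nascent_threshold)
  na_max <- max(actin, .Machine$double.eps)
  nn_max <- max(nascent, .Machine$double.eps)
  combined <- actin / na_max + nascent / nn_max
  fg <- (actin > thr_a) | (nascent > thr_n) | (seeds > 0L)
  terr <- cpp_watershed3d(max(combined) - combined, as.integer(seeds),
                          as.logical(fg), dims)
  terr <- array(terr, dims)

  # limit each territory to its seed's padded bounding box
  pad <- ceiling(config$crop_padding_um / vs)
  sidx <- which(seeds > 0L)
  szyx <- flat_to_zyx(sidx, dims)
  slab <- seeds[sidx]
  nlab <- attr(seeds, "n_objects")
  lo <- hi <- matrix(NA_integer_, nlab, 3)
  for (a in 1:3) {
    lo[, a] <- as.integer(tapply(szyx[, a], slab, min)) - pad[a]
    hi[, a] <- as.integer(tapply(szyx[, a], slab, max)) + pad[a]
  }
  tidx <- which(terr > 0L)
  tzyx <- flat_to_zyx(tidx, dims)
  tlab <- terr[tidx]
  ok <- tzyx[, 1] >= lo[tlab, 1] & tzyx[, 1] <= hi[tlab, 1] &
    tzyx[, 2] >= lo[tlab, 2] & tzyx[, 2] <= hi[tlab, 2] &
    tzyx[, 3] >= lo[tlab, 3] & tzyx[, 3] <= hi[tlab, 3]
  terr[tidx[!ok]] <- 0L
  label_volume(terr, dims, vs, nlab)
}
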