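#' Extracellular (pericellular matrix) mask by actin subtraction
#'
#' Subtracts the actin (cell body) mask from the nascent-protein mask,
#' leaving only signal deposited outside the cell: `nascent AND NOT actin`.
#' An empty result means the cell's nascent protein is restricted to the
#' intracellular region.
#'
#' @param nascent_mask,actin_mask logical arrays on one cell's crop grid,
#'   identical shape.
#' @return logical array: subset of `nascent_mask`, disjoint from
#'   `actin_mask`.
#' @export
extracellular_mask <- function(nascent_mask, actin_mask) {
  if (!identical(dim(nascent_mask), dim(actin_mask)))
    oc_abort("mask shapes differ", "invalid_input")
  nascent_mask & !actin_mask
}

#' Classify a cell by its nascent-protein deposition
#'
#' Three-way taxonomy: `negative` (no detectable nascent signal, below the
#' detection floor), `restricted` (signal present but the actin subtraction
#' is empty — deposition confined to the cell body), `secreting` (deposition
#' outside the cell body).
#'
#' @param total_nascent_voxels voxels of nascent signal in the cell.
#' @param ecm_voxels voxels of the extracellular mask; cannot exceed the
#'   total.
#' @param detection_min voxel floor below which the cell counts as negative.
#' @return one of `"negative"`, `"restricted"`, `"secreting"`.
#' @export
classify_cell <- function(total_nascent_voxels, ecm_voxels,
                          detection_min = 5) {
  if (total_nascent_voxels < 0 || ecm_voxels < 0)
    oc_abort("voxel counts must be >= 0", "invalid_input")
  if (ecm_voxels > total_nascent_voxels)
    oc_abort("extracellular voxels exceed total nascent voxels",
             "invariant_violation")
  if (total_nascent_voxels < detection_min) return("negative")
  if (ecm_voxels == 0) return("restricted")
  "secreting"
}

bbox_ranges <- function(zyx, dims, pad) {
  lo <- pmax(apply(zyx, 2, min) - pad, 1L)
  hi <- pmin(apply(zyx, 2, max) + pad, dims)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Quantify nascent-protein deposition per cell across a stack
#'
#' The full single-cell workflow: nuclei segmentation, seeded territory
#' assignment, per-cell crop, actin-mask subtraction, classification, and
#' volume quantification (voxel count times voxel volume). Cells whose
#' territory touches the lateral (y/x) stack border are flagged
#' `border_touching`; they stay in the class counts but should be excluded
#' from volume statistics (their volumes are truncated).
#'
#' @param stack an [image_stack()] with `nuclei`, `actin` and `nascent`
#'   roles (optionally `collagen1` / `collagen2`).
#' @param config an [analysis_config()].
#' @return list with `cells` (one row per cell: centroid, voxel counts,
#'   volumes in um^3, mean intensities, class, border flag, collagen
#'   positivity when measured) and `summary` (cell count, class counts and
#'   fractions over all retained cells).
#' @export
quantify_stack <- function(stack, config = analysis_config()) {
  seeds <- segment_nuclei(stack, config)
  n <- attr(seeds, "n_objects")
  vv <- voxel_volume(stack)
  if (n == 0)
    return(list(cells = data.frame(), summary = list(
      n_cells = 0L, class_counts = c(negative = 0L, restricted = 0L,
                                     secreting = 0L),
      class_fractions = c(negative = NA_real_, restricted = NA_real_,
                          secreting = NA_real_))))
  terr <- assign_cell_territories(seeds, stack, config)
  dims <- dim(terr)
  actin <- stack_channel(stack, "actin")
  nascent <- stack_channel(stack, "nascent")
  thr_a <- oc_threshold(actin, config$actin_threshold)
  thr_n <- oc_threshold(nascent, config$nascent_threshold)
  cents <- label_centroids(seeds)
  pad <- ceiling(config$crop_padding_um / stack$voxel_size)

  tidx <- which(terr > 0L)
  tlab <- terr[tidx]
  tz <- split(tidx, tlab)

  has_col <- "collagen1" %in% names(stack$channel_roles)
  if (has_col) {
    collagen <- stack_channel(stack, "collagen1")
    thr_c <- oc_threshold(collagen, config$collagen_threshold)
  }

  rows <- vector("list", n)
  for (id in seq_len(n)) {
    vox_id <- tz[[as.character(id)]]
    if (is.null(vox_id)) vox_id <- integer()
    if (length(vox_id) == 0) {
      rows[[id]] <- data.frame(
        cell_id = id, centroid_z_um = cents$z_um[cents$label == id],
        centroid_y_um = cents$y_um[cents$label == id],
        centroid_x_um = cents$x_um[cents$label == id],
        total_nascent_voxels = 0L, extracellular_voxels = 0L,
        actin_voxels = 0L, total_nascent_volume_um3 = 0,
        extracellular_volume_um3 = 0, actin_volume_um3 = 0,
        mean_nascent_intensity = NA_real_, class = "negative",
        border_touching = FALSE,
        collagen1_positive = if (has_col) FALSE else NA)
      next
    }
    zyx <- flat_to_zyx(vox_id, dims)
    in_cell_nasc <- nascent[vox_id] > thr_n
    in_cell_act <- actin[vox_id] > thr_a
    ecm <- extracellular_mask(in_cell_nasc, in_cell_act)
    tot <- sum(in_cell_nasc)
    ne <- sum(ecm)
    cls <- classify_cell(tot, ne, config$detection_min_voxels)
    border <- any(zyx[, 2] == 1L | zyx[, 2] == dims[2] |
                    zyx[, 3] == 1L | zyx[, 3] == dims[3])
    rows[[id]] <- data.frame(
      cell_id = id, centroid_z_um = cents$z_um[cents$label == id],
      centroid_y_um = cents$y_um[cents$label == id],
      centroid_x_um = cents$x_um[cents$label == id],
      total_nascent_voxels = tot, extracellular_voxels = ne,
      actin_voxels = sum(in_cell_act),
      total_nascent_volume_um3 = tot * vv,
      extracellular_volume_um3 = ne * vv,
      actin_volume_um3 = sum(in_cell_act) * vv,
      mean_nascent_intensity =
        if (tot > 0) mean(nascent[vox_id][in_cell_nasc]) else NA_real_,
      class = cls, border_touching = border,
      collagen1_positive =
        if (has_col) sum(collagen[vox_id] > thr_c) >= 5L else NA)
  }
  cells <- do.call(rbind, rows)
  cls_lv <- c("negative", "restricted", "secreting")
  counts <- table(factor(cells$class, levels = cls_lv))
  list(cells = cells,
       summary = list(n_cells = nrow(cells),
                      class_counts = setNames(as.integer(counts), cls_lv),
                      class_fractions = setNames(
                        as.numeric(counts) / nrow(cells), cls_lv),
                      voxel_volume_um3 = vv))
}

#' Fraction of cells positive for a collagen channel
#'
#' A cell is positive when its territory contains at least `min_overlap`
#' voxels above the channel threshold; the fraction is positives over the
#' total number of segmented nuclei, as a percentage.
#'
#' @param stack an [image_stack()] with the named collagen role.
#' @param territories a `label_volume` of cell territories (one per nucleus).
#' @param role `"collagen1"` or `"collagen2"`.
#' @param threshold `"otsu"` or a fixed intensity.
#' @param min_overlap minimum above-threshold voxels for positivity.
#' @return percentage in `[0, 100]`.
#' @export
collagen_positive_fraction <- function(stack, territories, role = "collagen1",
                                       threshold = "otsu", min_overlap = 5) {
  n <- attr(territories, "n_objects")
  if (is.null(n) || n < 1)
    oc_abort("no segmented nuclei: fraction undefined", "undefined_fraction")
  v <- stack_channel(stack, role)
  thr <- oc_threshold(v, threshold)
  idx <- which(territories > 0L)
  above <- tapply(v[idx] > thr, territories[idx], sum)
  pos <- sum(above >= min_overlap)
  100 * pos / n
}

#' Live/dead viability from a two-channel image
#'
#' Counts stained objects in the live (calcein-AM) and dead (ethidium
#' homodimer) channels by threshold, 26-connected components and a minimum
#' object volume. Objects positive in both channels (majority of the live
#' object's voxels inside the dead mask) are counted once, as dead.
#' Viability is `100 * live / (live + dead)`.
#'
#' @param stack an [image_stack()] with `live` and `dead` roles.
#' @param config an [analysis_config()] (`min_object_volume_um3` and the
#'   channel thresholds; live/dead use the nuclei threshold setting).
#' @return list: `viability_percent`, `n_live`, `n_dead`,
#'   `n_double_positive`.
#' @export
quantify_viability <- function(stack, config = analysis_config()) {
  dims <- dim(stack$voxels)[2:4]
  vv <- voxel_volume(stack)
  minvox <- max(1, ceiling(config$min_object_volume_um3 / vv))
  count_channel <- function(role) {
    v <- stack_channel(stack, role)
    thr <- oc_threshold(v, config$nuclei_threshold)
    mask <- v > thr
    lab <- cpp_label3d(as.logical(mask), dims)
    counts <- tabulate(lab[lab > 0L])
    keep <- which(counts >= minvox)
    list(labels = array(lab, dims), keep = keep, mask = mask)
  }
  live <- count_channel("live")
  dead <- count_channel("dead")
  n_live_raw <- length(live$keep)
  n_dead <- length(dead$keep)
  dbl <- 0L
  if (n_live_raw > 0 && any(dead$mask)) {
    idx <- which(live$labels > 0L)
    lb <- live$labels[idx]
    sel <- lb %in% live$keep
    overlap <- tapply(dead$mask[idx[sel]], lb[sel], mean)
    dbl <- sum(overlap >= 0.5)
  }
  n_live <- n_live_raw - dbl
  if (n_live + n_dead == 0)
    oc_abort("no stained cells detected: viability undefined",
             "undefined_fraction")
  list(viability_percent = 100 * n_live / (n_live + n_dead),
       n_live = n_live, n_dead = n_dead, n_double_positive = dbl)
}
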