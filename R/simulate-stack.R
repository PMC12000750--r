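#' Phenotype parameters for the synthetic cell-stack generator
#'
#' Describes the cell population rendered by [generate_cell_stack()]: the
#' three-way deposition taxonomy (negative / restricted / secreting), cell
#' geometry, channel intensities and the noise model. Cells are geometric
#' idealizations: an ellipsoidal nucleus, a filled cell body whose outer
#' boundary lies one cortical-shell thickness beyond the nucleus (rendered in
#' the actin channel), and for secreting cells a pericellular shell of
#' nascent signal outside the cell body.
#'
#' @param n_cells number of cells to place (>= 1).
#' @param fractions named proportions of `negative`, `restricted`,
#'   `secreting` cells; non-negative, summing to 1.
#' @param nucleus_radius_um mean and sd of the nucleus equatorial radius.
#' @param nucleus_axis_ratio_z axial (z) semi-axis as a fraction of the
#'   equatorial radius (nuclei are slightly oblate in gels).
#' @param actin_thickness_um cortical shell thickness: the cell body extends
#'   this far beyond the nucleus.
#' @param pericellular_thickness_um thickness of the nascent-protein shell
#'   deposited outside the cell body (secreting cells only).
#' @param intensity_nuclei,intensity_actin channel intensities (a.u., on a
#'   `[0, 1]` scale).
#' @param intensity_nascent_intra,intensity_nascent_peri nascent-channel
#'   intensity inside the cell body and in the pericellular shell.
#' @param collagen_positive_fraction fraction of cells depositing collagen
#'   (adds a `collagen1` channel when > 0).
#' @param intensity_collagen collagen channel intensity.
#' @param noise_sd additive Gaussian noise sd (a.u.); applied last.
#' @param poisson_scale if > 0, photon-counting noise: intensities are
#'   replaced by `rpois(intensity * scale) / scale` before Gaussian noise.
#' @param shape stack shape `(nz, ny, nx)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param min_gap_um minimum surface-to-surface distance between cells.
#' @return a validated list of class `phenotype_params`.
#' @export
phenotype_params <- function(n_cells = 100,
                             fractions = c(negative = 0.2, restricted = 0.3,
                                           secreting = 0.5),
                             nucleus_radius_um = c(mean = 4, sd = 0.4),
                             nucleus_axis_ratio_z = 0.8,
                             actin_thickness_um = 2,
                             pericellular_thickness_um = 2,
                             intensity_nuclei = 0.9,
                             intensity_actin = 0.7,
                             intensity_nascent_intra = 0.8,
                             intensity_nascent_peri = 0.6,
                             collagen_positive_fraction = 0,
                             intensity_collagen = 0.7,
                             noise_sd = 0.02,
                             poisson_scale = 0,
                             shape = c(30, 448, 448),
                             voxel_size = c(2, 0.42, 0.42),
                             min_gap_um = 1) {
  if (n_cells < 1) oc_abort("`n_cells` must be >= 1", "invalid_input")
  fr <- fractions[c("negative", "restricted", "secreting")]
  if (any(is.na(fr)) || any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    oc_abort("`fractions` must be named non-negative proportions summing to 1",
             "invalid_input")
  if (nucleus_radius_um[["mean"]] <= 0 || actin_thickness_um <= 0 ||
      pericellular_thickness_um <= 0 || nucleus_axis_ratio_z <= 0)
    oc_abort("radii and thicknesses must be > 0", "invalid_input")
  structure(list(n_cells = as.integer(n_cells), fractions = fr,
                 nucleus_radius_um = nucleus_radius_um,
                 nucleus_axis_ratio_z = nucleus_axis_ratio_z,
                 actin_thickness_um = actin_thickness_um,
                 pericellular_thickness_um = pericellular_thickness_um,
                 intensity_nuclei = intensity_nuclei,
                 intensity_actin = intensity_actin,
                 intensity_nascent_intra = intensity_nascent_intra,
                 intensity_nascent_peri = intensity_nascent_peri,
                 collagen_positive_fraction = collagen_positive_fraction,
                 intensity_collagen = intensity_collagen,
                 noise_sd = noise_sd, poisson_scale = poisson_scale,
                 shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 min_gap_um = min_gap_um),
            class = c("phenotype_params", "list"))
}

# Voxel-centre coordinates (um) along one axis.
axis_coords <- function(n, step) (seq_len(n) - 0.5) * step

# Logical mask of an axis-aligned ellipsoid on a voxel-grid crop.
ellipsoid_mask <- function(zc, yc, xc, centre, semi) {
  ez <- ((zc - centre[1]) / semi[1])^2
  ey <- ((yc - centre[2]) / semi[2])^2
  ex <- ((xc - centre[3]) / semi[3])^2
  outer(outer(ez, ey, `+`), ex, `+`) <= 1
}

#' Generate a ground-truthed 3D cell stack
#'
#' Renders `n_cells` non-touching idealized cells into a multi-channel stack
#' (channels: nuclei, actin, nascent, optionally collagen1) and returns the
#' per-cell ground truth computed from the noiseless geometry. Class labels
#' are drawn first from the seeded RNG (a multinomial draw in cell order), so
#' the realized class counts are replayable from the seed.
#'
#' @param p a [phenotype_params()].
#' @param seed integer RNG seed; same seed and parameters give bit-identical
#'   output.
#' @return list with `stack` (an [image_stack()]) and `truth` (data frame:
#'   `cell_id`, `class`, centroid in um, nucleus / total-nascent /
#'   extracellular voxel counts and volumes, collagen positivity).
#' @export
generate_cell_stack <- function(p = phenotype_params(), seed = 1L) {
  set.seed(seed)
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  vs <- p$voxel_size
  extent <- c(nz, ny, nx) * vs            # (z, y, x) in um
  classes <- sample(c("negative", "restricted", "secreting"),
                    p$n_cells, replace = TRUE, prob = p$fractions)
  radii <- rnorm(p$n_cells, p$nucleus_radius_um[["mean"]],
                 p$nucleus_radius_um[["sd"]])
  radii <- pmax(radii, 0.5 * p$nucleus_radius_um[["mean"]])
  collagen_pos <- runif(p$n_cells) < p$collagen_positive_fraction

  outer_r <- radii + p$actin_thickness_um + p$pericellular_thickness_um
  outer_rz <- radii * p$nucleus_axis_ratio_z + p$actin_thickness_um +
    p$pericellular_thickness_um
  centres <- matrix(NA_real_, p$n_cells, 3)  # (z, y, x) um
  budget <- 200L * p$n_cells
  placed <- 0L
  while (placed < p$n_cells && budget > 0L) {
    budget <- budget - 1L
    i <- placed + 1L
    mz <- outer_rz[i] + vs[1]; mxy <- outer_r[i] + vs[2]
    if (2 * mz >= extent[1] || 2 * mxy >= extent[2] || 2 * mxy >= extent[3])
      oc_abort("stack too small for the requested cell geometry",
               "geometry_infeasible")
    cand <- c(runif(1, mz, extent[1] - mz),
              runif(1, mxy, extent[2] - mxy),
              runif(1, mxy, extent[3] - mxy))
    ok <- TRUE
    if (placed > 0L) {
      dd <- sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) -
                            cand)^2))
      ok <- all(dd >= outer_r[seq_len(placed)] + outer_r[i] + p$min_gap_um)
    }
    if (ok) {
      centres[i, ] <- cand
      placed <- i
    }
  }
  if (placed < p$n_cells)
    oc_abort(sprintf(
      "could not place %d non-overlapping cells (placed %d); enlarge the stack",
      p$n_cells, placed), "geometry_infeasible")

  has_collagen <- p$collagen_positive_fraction > 0
  n_ch <- if (has_collagen) 4L else 3L
  roles <- c(nuclei = 1L, actin = 2L, nascent = 3L)
  if (has_collagen) roles <- c(roles, collagen1 = 4L)
  vox <- array(0, dim = c(n_ch, nz, ny, nx))
  zc_all <- axis_coords(nz, vs[1])
  yc_all <- axis_coords(ny, vs[2])
  xc_all <- axis_coords(nx, vs[3])

  truth <- data.frame(cell_id = seq_len(p$n_cells), class = classes,
                      centroid_z_um = NA_real_, centroid_y_um = NA_real_,
                      centroid_x_um = NA_real_, nucleus_voxels = NA_integer_,
                      total_nascent_voxels = 0L, extracellular_voxels = 0L,
                      collagen1_positive = collagen_pos & has_collagen,
                      stringsAsFactors = FALSE)

  for (i in seq_len(p$n_cells)) {
    r <- radii[i]; ct <- centres[i, ]
    semi_nuc <- c(r * p$nucleus_axis_ratio_z, r, r)
    semi_body <- semi_nuc + p$actin_thickness_um
    semi_peri <- semi_body + p$pericellular_thickness_um
    iz <- which(abs(zc_all - ct[1]) <= semi_peri[1] + vs[1])
    iy <- which(abs(yc_all - ct[2]) <= semi_peri[2] + vs[2])
    ix <- which(abs(xc_all - ct[3]) <= semi_peri[3] + vs[3])
    zc <- zc_all[iz]; yc <- yc_all[iy]; xc <- xc_all[ix]
    m_nuc <- ellipsoid_mask(zc, yc, xc, ct, semi_nuc)
    m_body <- ellipsoid_mask(zc, yc, xc, ct, semi_body)
    m_peri <- ellipsoid_mask(zc, yc, xc, ct, semi_peri) & !m_body

    add <- function(ch, mask, val) {
      sub <- vox[ch, iz, iy, ix, drop = FALSE]
      dim(sub) <- dim(mask)
      sub[mask] <- val
      vox[ch, iz, iy, ix] <<- sub
    }
    add(1L, m_nuc, p$intensity_nuclei)
    add(2L, m_body, p$intensity_actin)
    cls <- classes[i]
    if (cls != "negative") add(3L, m_body, p$intensity_nascent_intra)
    if (cls == "secreting") add(3L, m_peri, p$intensity_nascent_peri)
    if (has_collagen && collagen_pos[i])
      add(4L, m_body | m_peri, p$intensity_collagen)

    nuc_idx <- which(m_nuc, arr.ind = TRUE)
    truth$centroid_z_um[i] <- mean(zc[nuc_idx[, 1]])
    truth$centroid_y_um[i] <- mean(yc[nuc_idx[, 2]])
    truth$centroid_x_um[i] <- mean(xc[nuc_idx[, 3]])
    truth$nucleus_voxels[i] <- sum(m_nuc)
    if (cls != "negative")
      truth$total_nascent_voxels[i] <- sum(m_body) +
        if (cls == "secreting") sum(m_peri) else 0L
    if (cls == "secreting") truth$extracellular_voxels[i] <- sum(m_peri)
  }
  vv <- prod(vs)
  truth$total_nascent_volume_um3 <- truth$total_nascent_voxels * vv
  truth$extracellular_volume_um3 <- truth$extracellular_voxels * vv

  if (p$poisson_scale > 0)
    vox[] <- rpois(length(vox), vox * p$poisson_scale) / p$poisson_scale
  if (p$noise_sd > 0)
    vox[] <- pmax(vox + rnorm(length(vox), 0, p$noise_sd), 0)

  list(stack = image_stack(vox, voxel_size = vs, channel_roles = roles),
       truth = truth)
}

#' Generate a ground-truthed live/dead viability image
#'
#' Renders spherical cells into a thin two-channel stack (roles `live`,
#' `dead`). Dead cells appear in the dead channel; a configurable fraction of
#' them is additionally rendered in the live channel (membrane-compromised
#' double positives, which the counting rule must classify as dead).
#'
#' @param n_cells number of cells (the viability workflow is validated at
#'   >= 250 cells per image).
#' @param frac_live fraction of live cells.
#' @param exact_counts if `TRUE`, exactly `round(frac_live * n_cells)` cells
#'   are live (a counted toy input); otherwise each cell is live
#'   independently with probability `frac_live`.
#' @param double_positive_frac fraction of dead cells also visible in the
#'   live channel.
#' @param cell_radius_um sphere radius.
#' @param intensity signal intensity (a.u.).
#' @param noise_sd additive Gaussian noise sd.
#' @param shape stack shape `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` um; the default emulates a low-power
#'   widefield field of view.
#' @param seed RNG seed.
#' @return list with `stack` (an [image_stack()]) and `truth`
#'   (`n_live`, `n_dead`, `viability_percent`, per-cell table).
#' @export
generate_viability_stack <- function(n_cells = 300, frac_live = 0.9,
                                     exact_counts = FALSE,
                                     double_positive_frac = 0,
                                     cell_radius_um = 3,
                                     intensity = 0.8, noise_sd = 0.02,
                                     shape = c(3, 400, 400),
                                     voxel_size = c(5, 1.5, 1.5),
                                     seed = 1L) {
  set.seed(seed)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  vs <- voxel_size
  extent <- c(nz, ny, nx) * vs
  alive <- if (exact_counts) {
    n_live <- round(frac_live * n_cells)
    sample(rep(c(TRUE, FALSE), c(n_live, n_cells - n_live)))
  } else runif(n_cells) < frac_live
  dbl <- !alive & (runif(n_cells) < double_positive_frac)
  centres <- matrix(NA_real_, n_cells, 3)
  placed <- 0L; budget <- 200L * n_cells
  r <- cell_radius_um
  while (placed < n_cells && budget > 0L) {
    budget <- budget - 1L
    cand <- c(runif(1, min(r, extent[1] / 2), max(extent[1] - r, extent[1] / 2)),
              runif(1, r, extent[2] - r), runif(1, r, extent[3] - r))
    ok <- placed == 0L ||
      all(sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) -
                          cand)^2)) >= 2 * r + 1)
    if (ok) { placed <- placed + 1L; centres[placed, ] <- cand }
  }
  if (placed < n_cells)
    oc_abort("could not place all viability cells; enlarge the image",
             "geometry_infeasible")
  vox <- array(0, dim = c(2L, nz, ny, nx))
  zc_all <- axis_coords(nz, vs[1]); yc_all <- axis_coords(ny, vs[2])
  xc_all <- axis_coords(nx, vs[3])
  for (i in seq_len(n_cells)) {
    ct <- centres[i, ]
    iz <- which(abs(zc_all - ct[1]) <= r + vs[1])
    iy <- which(abs(yc_all - ct[2]) <= r + vs[2])
    ix <- which(abs(xc_all - ct[3]) <= r + vs[3])
    m <- ellipsoid_mask(zc_all[iz], yc_all[iy], xc_all[ix], ct, c(r, r, r))
    chs <- if (alive[i]) 1L else if (dbl[i]) c(1L, 2L) else 2L
    for (ch in chs) {
      sub <- vox[ch, iz, iy, ix, drop = FALSE]
      dim(sub) <- dim(m)
      sub[m] <- intensity
      vox[ch, iz, iy, ix] <- sub
    }
  }
  if (noise_sd > 0) vox[] <- pmax(vox + rnorm(length(vox), 0, noise_sd), 0)
  truth <- data.frame(cell_id = seq_len(n_cells), alive = alive,
                      double_positive = dbl)
  list(stack = image_stack(vox, voxel_size = vs,
                           channel_roles = c(live = 1L, dead = 2L)),
       truth = list(cells = truth, n_live = sum(alive),
                    n_dead = sum(!alive),
                    viability_percent = 100 * sum(alive) / n_cells))
}
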