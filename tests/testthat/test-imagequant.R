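test_that("an empty nuclei channel yields zero objects with a warning", {
  vox <- array(0, dim = c(3, 6, 20, 20))
  st <- image_stack(vox, channel_roles = c(nuclei = 1L, actin = 2L,
                                           nascent = 3L))
  expect_warning(seg <- segment_nuclei(st, analysis_config()),
                 class = "osteochip_empty_segmentation")
  expect_identical(attr(seg, "n_objects"), 0L)
})

test_that("noiseless nuclei are recovered with matching centroids", {
  g <- small_noiseless_stack(n_cells = 10, seed = 21)
  seg <- segment_nuclei(g$stack, analysis_config())
  expect_identical(attr(seg, "n_objects"), 10L)
  cen <- label_centroids(seg)
  m <- match_to_truth(data.frame(centroid_z_um = cen$z_um,
                                 centroid_y_um = cen$y_um,
                                 centroid_x_um = cen$x_um), g$truth)
  expect_identical(sort(m), 1:10)
  vs <- g$stack$voxel_size
  expect_true(all(abs(cen$z_um - g$truth$centroid_z_um[m]) <= vs[1]))
  expect_true(all(abs(cen$y_um - g$truth$centroid_y_um[m]) <= vs[2]))
  expect_true(all(abs(cen$x_um - g$truth$centroid_x_um[m]) <= vs[3]))
})

test_that("touching nuclei are split by the distance-transform watershed", {
  # two spheres merged into one blob: centres 7 um apart, radius 4 um
  vox <- array(0, dim = c(1, 16, 60, 60))
  zc <- (seq_len(16) - 0.5) * 2
  yc <- xc <- (seq_len(60) - 0.5) * 0.42
  for (centre in list(c(16, 12, 12.6), c(16, 12, 19.6))) {
    m <- outer(outer(((zc - centre[1]) / 3.2)^2, ((yc - centre[2]) / 4)^2,
                     `+`), ((xc - centre[3]) / 4)^2, `+`) <= 1
    v <- array(vox[1, , , ], dim = c(16, 60, 60))
    v[m] <- 0.9
    vox[1, , , ] <- pmax(array(vox[1, , , ], dim = c(16, 60, 60)), v)
  }
  st <- image_stack(vox, channel_roles = c(nuclei = 1L))
  # oracle: the blob is one 26-connected component but holds 2 seeds
  blob <- label3d_reference(stack_channel(st, "nuclei") > 0.5)
  expect_identical(max(blob), 1L)
  seg <- segment_nuclei(st, analysis_config())
  expect_identical(attr(seg, "n_objects"), 2L)
})

test_that("cell territories partition the foreground", {
  g <- small_noiseless_stack(n_cells = 8, seed = 31)
  cfg <- analysis_config()
  seeds <- segment_nuclei(g$stack, cfg)
  terr <- assign_cell_territories(seeds, g$stack, cfg)
  act <- stack_channel(g$stack, "actin") > 0
  nas <- stack_channel(g$stack, "nascent") > 0
  # every rendered foreground voxel carries exactly one label
  expect_true(all(terr[act | nas] > 0))
  expect_identical(length(unique(as.integer(terr[terr > 0]))),
                   attr(seeds, "n_objects"))
  # distant cells map onto their own seed: voxel counts match ground truth
  cnt <- table(terr[nas])
  expect_identical(sum(cnt), sum(g$truth$total_nascent_voxels))
})

test_that("extracellular mask is the set difference of nascent and actin", {
  nas <- array(FALSE, c(4, 5, 5)); nas[1:4, 1:5, 1:5][1:100] <- TRUE
  act <- array(FALSE, c(4, 5, 5)); act[1:60] <- TRUE
  ecm <- extracellular_mask(nas, act)
  expect_identical(sum(ecm), 40L)
  expect_true(all(which(ecm) %in% which(nas)))
  expect_identical(sum(ecm & act), 0L)
  expect_identical(sum(extracellular_mask(act & FALSE, act)), 0L)
  # nascent fully inside actin: empty subtraction
  expect_identical(sum(extracellular_mask(act, nas)), 0L)
  expect_error(extracellular_mask(nas, array(FALSE, c(4, 5, 4))),
               class = "osteochip_invalid_input")
})

test_that("cells classify by detection floor and empty subtraction", {
  expect_identical(classify_cell(0, 0, 5), "negative")
  expect_identical(classify_cell(4, 0, 5), "negative")
  expect_identical(classify_cell(500, 0, 5), "restricted")
  expect_identical(classify_cell(500, 120, 5), "secreting")
  expect_error(classify_cell(10, 20, 5),
               class = "osteochip_invariant_violation")
})

test_that("raising the detection floor only moves cells toward negative", {
  rank_of <- c(negative = 1, restricted = 2, secreting = 3)
  set.seed(7)
  for (i in 1:50) {
    tot <- sample(0:400, 1)
    ecm <- sample(0:tot, 1)
    cls <- sapply(c(1, 5, 50, 500), function(dm) classify_cell(tot, ecm, dm))
    expect_true(all(diff(rank_of[cls]) <= 0))
  }
})

test_that("noiseless volumes equal ground truth exactly", {
  g <- small_noiseless_stack(n_cells = 12, seed = 41)
  q <- quantify_stack(g$stack, analysis_config())
  expect_identical(q$summary$n_cells, 12L)
  m <- match_to_truth(q$cells, g$truth)
  expect_identical(sort(m), 1:12)
  expect_identical(q$cells$total_nascent_voxels,
                   g$truth$total_nascent_voxels[m])
  expect_identical(q$cells$extracellular_voxels,
                   g$truth$extracellular_voxels[m])
  expect_equal(q$cells$total_nascent_volume_um3,
               g$truth$total_nascent_voxels[m] * voxel_volume(g$stack))
  expect_identical(q$cells$class, g$truth$class[m])
  # per-record invariant and partition property
  expect_true(all(q$cells$extracellular_volume_um3 <=
                    q$cells$total_nascent_volume_um3))
  expect_equal(sum(q$summary$class_fractions), 1)
})

test_that("volumes are invariant to whole-voxel stack translation", {
  g <- small_noiseless_stack(n_cells = 6, seed = 51)
  q1 <- quantify_stack(g$stack, analysis_config())
  d <- dim(g$stack$voxels)
  shifted <- array(0, d)
  shifted[, 2:d[2], 4:d[3], 6:d[4]] <-
    g$stack$voxels[, 1:(d[2] - 1), 1:(d[3] - 3), 1:(d[4] - 5)]
  st2 <- image_stack(shifted, voxel_size = g$stack$voxel_size,
                     channel_roles = g$stack$channel_roles)
  q2 <- quantify_stack(st2, analysis_config())
  expect_identical(sort(q1$cells$total_nascent_voxels),
                   sort(q2$cells$total_nascent_voxels))
  expect_identical(sort(q1$cells$extracellular_voxels),
                   sort(q2$cells$extracellular_voxels))
})

test_that("class fractions are recovered within 5 points under noise", {
  errs <- sapply(1:2, function(s) {
    g <- generate_cell_stack(
      phenotype_params(n_cells = 60, shape = c(28, 360, 360),
                       noise_sd = 0.02), seed = s)
    q <- quantify_stack(g$stack, analysis_config())
    truth_fr <- table(factor(g$truth$class,
                             c("negative", "restricted", "secreting"))) / 60
    max(abs(q$summary$class_fractions - as.numeric(truth_fr)))
  })
  expect_true(all(errs <= 0.05))
})

test_that("collagen positivity fraction follows its printed definition", {
  g <- small_noiseless_stack(n_cells = 12, seed = 61,
                             collagen_positive_fraction = 0.4)
  cfg <- analysis_config()
  seeds <- segment_nuclei(g$stack, cfg)
  terr <- assign_cell_territories(seeds, g$stack, cfg)
  pct <- collagen_positive_fraction(g$stack, terr, "collagen1",
                                    threshold = 0.3)
  expect_equal(pct, 100 * sum(g$truth$collagen1_positive) / 12)
  empty <- terr; attr(empty, "n_objects") <- 0L
  expect_error(collagen_positive_fraction(g$stack, empty, "collagen1"),
               class = "osteochip_undefined_fraction")
})

test_that("zero collagen signal gives a zero positive fraction", {
  g <- small_noiseless_stack(n_cells = 5, seed = 62,
                             collagen_positive_fraction = 1e-9)
  # collagen channel present but no positive cells drawn
  expect_true(all(stack_channel(g$stack, "collagen1") == 0))
  cfg <- analysis_config()
  seeds <- segment_nuclei(g$stack, cfg)
  terr <- assign_cell_territories(seeds, g$stack, cfg)
  expect_identical(collagen_positive_fraction(g$stack, terr, "collagen1",
                                              threshold = 0.3), 0)
})

test_that("viability follows live / (live + dead) on counted images", {
  v <- generate_viability_stack(n_cells = 100, frac_live = 0.8,
                                noise_sd = 0, seed = 8)
  q <- quantify_viability(v$stack, analysis_config())
  expect_identical(q$n_live, v$truth$n_live)
  expect_identical(q$n_dead, v$truth$n_dead)
  expect_equal(q$viability_percent, v$truth$viability_percent)
  # all dead
  v0 <- generate_viability_stack(n_cells = 40, frac_live = 0,
                                 noise_sd = 0, seed = 9)
  expect_equal(quantify_viability(v0$stack)$viability_percent, 0)
})

test_that("double-positive objects are counted once, as dead", {
  v <- generate_viability_stack(n_cells = 60, frac_live = 0.5,
                                double_positive_frac = 1, noise_sd = 0,
                                seed = 10)
  q <- quantify_viability(v$stack, analysis_config())
  expect_identical(q$n_double_positive, v$truth$n_dead)
  expect_identical(q$n_live, v$truth$n_live)
  expect_identical(q$n_dead, v$truth$n_dead)
})

test_that("an unstained image leaves viability undefined", {
  vox <- array(0, dim = c(2, 2, 30, 30))
  st <- image_stack(vox, voxel_size = c(5, 1.5, 1.5),
                    channel_roles = c(live = 1L, dead = 2L))
  expect_error(quantify_viability(st, analysis_config()),
               class = "osteochip_undefined_fraction")
})
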