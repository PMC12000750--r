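test_that("all-negative populations have zero nascent ground truth", {
  g <- small_noiseless_stack(n_cells = 5, fractions = c(negative = 1,
                                                        restricted = 0,
                                                        secreting = 0))
  expect_true(all(g$truth$total_nascent_volume_um3 == 0))
  expect_true(all(g$truth$extracellular_volume_um3 == 0))
  expect_true(all(stack_channel(g$stack, "nascent") == 0))
})

test_that("all-secreting noiseless rendering matches its own ground truth", {
  g <- small_noiseless_stack(n_cells = 5, fractions = c(negative = 0,
                                                        restricted = 0,
                                                        secreting = 1))
  expect_true(all(g$truth$extracellular_voxels > 0))
  nas <- stack_channel(g$stack, "nascent") > 0
  act <- stack_channel(g$stack, "actin") > 0
  # rendered pericellular shell voxels = declared extracellular ground truth
  expect_identical(sum(nas & !act), sum(g$truth$extracellular_voxels))
  expect_identical(sum(nas), sum(g$truth$total_nascent_voxels))
  expect_true(all(g$truth$extracellular_voxels <=
                    g$truth$total_nascent_voxels))
})

test_that("class labels replay the seeded multinomial draw", {
  p <- phenotype_params(n_cells = 30, fractions = c(negative = 0.2,
                                                    restricted = 0.3,
                                                    secreting = 0.5),
                        shape = c(26, 280, 280), noise_sd = 0)
  g <- generate_cell_stack(p, seed = 99)
  set.seed(99)
  replay <- sample(c("negative", "restricted", "secreting"), 30,
                   replace = TRUE, prob = c(0.2, 0.3, 0.5))
  expect_identical(g$truth$class, replay)
})

test_that("stack generation is bit-reproducible for a fixed seed", {
  p <- phenotype_params(n_cells = 4, shape = c(18, 120, 120))
  a <- generate_cell_stack(p, seed = 5)
  b <- generate_cell_stack(p, seed = 5)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
})

test_that("infeasible geometry raises a distinct error", {
  p <- phenotype_params(n_cells = 50, shape = c(10, 40, 40))
  expect_error(generate_cell_stack(p, seed = 1),
               class = "osteochip_geometry_infeasible")
})

test_that("the Hertz forward model evaluates the contact law", {
  # closed form: (4/3) * 20e3/0.75 * sqrt(25e-6) * (4e-6)^1.5
  expect_equal(hertz_force(4, 20e3, 0.5, 25), 1.4222e-6,
               tolerance = 1e-4)
  expect_identical(hertz_force(0, 20e3, 0.5, 25), 0)
  expect_identical(hertz_force(-1, 20e3, 0.5, 25), 0)
  d <- c(0.5, 1.7, 3.2)
  expect_equal(hertz_force(d, 30e3, 0.5, 25),
               2 * hertz_force(d, 15e3, 0.5, 25))
})

test_that("synthetic curves span baseline through max indentation", {
  cp <- curve_params(E_pa = 20e3, contact_offset_um = 2,
                     max_indentation_um = 5, noise_sd_n = 0)
  crv <- generate_indentation_curve(cp, seed = 1)
  pre <- crv$indentation_um < 2
  expect_true(all(crv$load_n[pre] == 0))
  expect_equal(max(crv$indentation_um), 7)
  expect_equal(crv$load_n[which.min(abs(crv$indentation_um - 6))],
               hertz_force(4, 20e3, 0.5, 25), tolerance = 1e-10)
})

test_that("the default cytokine design yields exactly 48 samples", {
  tab <- generate_cytokine_table(seed = 1)
  expect_identical(nrow(tab$values), 48L)
  expect_identical(ncol(tab$values), 20L)
  expect_identical(anyDuplicated(tab$sample_meta$sample_id), 0L)
  with(tab$sample_meta,
       expect_identical(nrow(unique(cbind(sex, condition, compartment,
                                          day))), 16L))
})

test_that("null designs have no condition effect beyond sampling error", {
  tab <- generate_cytokine_table(effects = default_cytokine_effects()[0, ],
                                 spike_fold = 1, missing_frac = 0,
                                 seed = 2)
  lv <- log(tab$values)
  infl <- tab$sample_meta$condition == "inflamed"
  dmeans <- colMeans(lv[infl, ]) - colMeans(lv[!infl, ])
  # group means of 24 samples with log-sd 0.35: se ~ 0.1
  expect_true(all(abs(dmeans) < 0.5))
})

test_that("declared effects raise the inflamed group mean", {
  tab <- generate_cytokine_table(seed = 3, missing_frac = 0)
  infl <- tab$sample_meta$condition == "inflamed"
  expect_gt(mean(tab$values[infl, "IL-6"]), mean(tab$values[!infl, "IL-6"]))
  expect_gt(mean(tab$values[infl, "IL-1 beta"]),
            5 * mean(tab$values[!infl, "IL-1 beta"]))
  expect_error(generate_cytokine_table(design = list(
    sex = "female", condition = "baseline", compartment = "osteoblast",
    day = 3, replicates = 0)), class = "osteochip_invalid_design")
  bad <- data.frame(analyte = "NOPE", factor = "condition",
                    level = "inflamed", fold = 2)
  expect_error(generate_cytokine_table(effects = bad),
               class = "osteochip_invalid_design")
})

test_that("diffusion frames honour the initial and equilibrium limits", {
  ser <- generate_diffusion_series(D_um2s = 100, noise_sd = 0)
  truth <- attr(ser, "truth")
  prof0 <- extract_profile(ser, 1)
  inside <- prof0$position_um > truth$channel_width_um + 5 &
    prof0$position_um < truth$channel_width_um + truth$chamber_width_um - 5
  src <- prof0$position_um < truth$channel_width_um - 5 |
    prof0$position_um > truth$channel_width_um + truth$chamber_width_um + 5
  expect_true(all(prof0$intensity[inside] == 0))
  expect_true(all(prof0$intensity[src] == truth$source_level))
  late <- generate_diffusion_series(D_um2s = 100, times_min = c(0, 6000),
                                    noise_sd = 0)
  profL <- extract_profile(late, 2)
  expect_true(all(abs(profL$intensity - 1) < 0.01))
})

test_that("generated profiles match the finite-difference transport oracle", {
  W <- 1200; D <- 100
  x <- seq(20, W - 20, by = 24)
  for (t_min in c(15, 30, 60, 150)) {
    ours <- diffusion_profile_analytic(x, t_min * 60, D, W)
    fd <- fd_diffusion_profile(x, t_min * 60, D, W)
    expect_lt(max(abs(ours - fd)), 0.01)
  }
})

test_that("noiseless frames converge monotonically at every interior pixel", {
  ser <- generate_diffusion_series(D_um2s = 80, noise_sd = 0)
  mat <- sapply(seq_along(ser$frames), function(i)
    extract_profile(ser, i)$intensity)
  expect_true(all(diff(t(mat)) >= -1e-12))
})
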