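toy_table <- function(values, mode = "concentration") {
  cytokine_table(values,
                 data.frame(sample_id = sprintf("S%d", seq_len(nrow(values)))),
                 mode = mode)
}

test_that("imputation replaces missing entries with 10% of the minimum", {
  v <- cbind(A = c(NA, 2, 5), B = c(1, 1, 1))
  out <- impute_missing(toy_table(v))
  expect_equal(out$values[, "A"], c(0.2, 2, 5))
  expect_equal(out$values[, "B"], c(1, 1, 1))
  # no missing values: identity
  full <- toy_table(cbind(A = c(1, 2, 3), B = c(4, 5, 6)))
  expect_identical(impute_missing(full)$values, full$values)
  # fully missing analyte is unimputable, named in the error
  bad <- toy_table(cbind(A = c(NA, NA, NA), B = c(1, 2, 3)))
  err <- expect_error(impute_missing(bad),
                      class = "osteochip_unimputable_analyte")
  expect_match(conditionMessage(err), "A")
})

test_that("the variance filter is strict at its threshold", {
  # column variances: 0 (constant), exactly 0.9, and > 0.9
  x_exact <- c(-1, 0, 1) * sqrt(0.9 / var(c(-1, 0, 1)))
  v <- cbind(const = c(3, 3, 3), edge = x_exact + 5, high = c(0, 4, 8))
  expect_equal(var(v[, "edge"]), 0.9)
  out <- filter_low_variance(toy_table(v), 0.9)
  expect_identical(out$removed, "const")
  expect_identical(colnames(out$table$values), c("edge", "high"))
  expect_error(filter_low_variance(toy_table(cbind(a = c(1, 1, 1))), 0.9),
               class = "osteochip_empty_table")
})

test_that("variance filtering matches direct per-column variances", {
  set.seed(14)
  v <- sapply(1:12, function(j) rnorm(30, sd = runif(1, 0.5, 1.5)))
  colnames(v) <- sprintf("A%02d", 1:12)
  out <- filter_low_variance(toy_table(v), 0.9)
  expect_identical(out$removed,
                   colnames(v)[apply(v, 2, var) < 0.9])
})

test_that("z-scoring standardizes, is idempotent and affine-invariant", {
  set.seed(15)
  v <- cbind(A = rnorm(20, 5, 3), B = runif(20), C = 1:20)
  z1 <- zscore_analytes(toy_table(v))
  expect_true(all(abs(colMeans(z1$values)) < 1e-9))
  expect_true(all(abs(apply(z1$values, 2, var) - 1) < 1e-9))
  z2 <- zscore_analytes(z1)
  expect_equal(unclass(z2$values), unclass(z1$values), tolerance = 1e-9)
  z3 <- zscore_analytes(toy_table(sweep(v * 2.7, 2, c(1, -4, 10), `+`)))
  expect_equal(unclass(z3$values), unclass(z1$values), tolerance = 1e-9)
  expect_error(zscore_analytes(toy_table(cbind(A = rep(1, 5), B = 1:5))),
               class = "osteochip_zero_variance")
})

test_that("rank-1 data loads entirely on the first component", {
  set.seed(16)
  t_lat <- rnorm(25)
  v <- cbind(A = 2 * t_lat, B = -1 * t_lat, C = 0.5 * t_lat)
  p <- pca_samples(toy_table(v))
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  expect_error(pca_samples(toy_table(v), exclude_analytes = c("A", "B")),
               class = "osteochip_undersized_input")
})

test_that("explained fractions equal the covariance eigenvalue ratios", {
  tab <- generate_cytokine_table(mode = "MFI", seed = 17)
  z <- zscore_analytes(impute_missing(tab))
  p <- pca_samples(z, exclude_analytes = c("IL-1 beta", "TNF alpha"))
  keep <- !(colnames(z$values) %in% c("IL-1 beta", "TNF alpha"))
  ev <- eigen(cov(z$values[, keep]), symmetric = TRUE)$values
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)
})

test_that("well-separated conditions split along PC1 with zero overlap", {
  tab <- generate_cytokine_table(mode = "MFI", response_sd = 0.1, seed = 18)
  z <- zscore_analytes(impute_missing(tab))
  p <- pca_samples(z, exclude_analytes = c("IL-1 beta", "TNF alpha"))
  sc <- p$scores[, 1]
  cnd <- tab$sample_meta$condition
  expect_true(max(sc[cnd == "baseline"]) < min(sc[cnd == "inflamed"]) ||
                min(sc[cnd == "baseline"]) > max(sc[cnd == "inflamed"]))
})

test_that("sample scores are invariant to analyte order up to sign fixing", {
  tab <- generate_cytokine_table(mode = "MFI", missing_frac = 0, seed = 19)
  z <- zscore_analytes(tab)
  p1 <- pca_samples(z)
  perm <- sample(ncol(z$values))
  z2 <- z; z2$values <- z$values[, perm]
  p2 <- pca_samples(z2)
  expect_equal(abs(p1$scores[, 1:5]), abs(p2$scores[, 1:5]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(p1$explained, p2$explained, tolerance = 1e-9)
})

test_that("contributions are normalized and rank designated drivers first", {
  set.seed(20)
  t_lat <- rnorm(30)
  v <- cbind(DRV = 3 * t_lat + rnorm(30, 0, 0.01),
             oth1 = rnorm(30, 0, 0.05), oth2 = rnorm(30, 0, 0.05))
  p <- pca_samples(toy_table(v))
  tc <- top_contributors(p, components = c(1, 2), n = 3)
  expect_identical(tc$analyte[1], "DRV")
  expect_gt(tc$contribution[1], 0.9)
  expect_equal(sum(top_contributors(p, c(1, 2),
                                    n = 3)$contribution), 1,
               tolerance = 1e-9)
  # three designated effect carriers occupy the top three ranks
  eff <- data.frame(analyte = c("IL-6", "IL-8", "MCP-1"),
                    factor = "condition", level = "inflamed",
                    fold = c(10, 8, 6))
  tab <- generate_cytokine_table(mode = "MFI", effects = eff,
                                 response_sd = 0.1, missing_frac = 0,
                                 seed = 1)
  pz <- pca_samples(zscore_analytes(tab),
                    exclude_analytes = c("IL-1 beta", "TNF alpha"))
  top3 <- top_contributors(pz, c(1, 2), 3)
  expect_setequal(top3$analyte, c("IL-6", "IL-8", "MCP-1"))
  expect_message(top_contributors(p, c(1, 2), n = 99), "returning all")
})

test_that("correlation clustering honours duplicates, negation and blocks", {
  set.seed(21)
  base <- rnorm(40)
  v <- cbind(A = base, Adup = base, Aneg = -base + 10,
             B = rnorm(40), C = rnorm(40))
  cl <- cluster_analytes(zscore_analytes(toy_table(v)))
  expect_equal(cl$correlation["A", "Adup"], 1, tolerance = 1e-12)
  expect_equal(diag(cl$correlation), rep(1, 5), ignore_attr = TRUE)
  expect_equal(max(abs(cl$correlation - t(cl$correlation))), 0)
  # duplicated pair merges at height 0
  first_merge <- cl$tree$merge[1, ]
  expect_setequal(colnames(v)[-first_merge], c("A", "Adup"))
  expect_equal(cl$tree$height[1], 0, tolerance = 1e-12)
  # distance to the negated analyte is maximal (2)
  expect_equal(1 - cl$correlation["A", "Aneg"], 2, tolerance = 1e-12)
  # merge heights are monotone non-decreasing (complete linkage)
  expect_true(all(diff(cl$tree$height) >= -1e-12))
})

test_that("a two-block correlation structure is recovered by a 2-cut", {
  tab <- generate_block_cytokine_table(n_samples = 48,
                                       block_sizes = c(5, 5), rho = 0.9,
                                       seed = 22)
  cl <- cluster_analytes(zscore_analytes(tab))
  cut <- cutree(cl$tree, k = 2)
  truth <- attr(tab, "blocks")
  expect_identical(length(unique(paste(cut, truth))), 2L)
})

test_that("cluster trees export as Newick text", {
  tab <- generate_block_cytokine_table(seed = 23)
  cl <- cluster_analytes(zscore_analytes(tab))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_cluster_newick(cl, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, colnames(tab$values))
})

test_that("the composed pipeline is deterministic and tracks exclusions", {
  mfi <- generate_cytokine_table(mode = "MFI", seed = 24)
  conc <- generate_cytokine_table(seed = 25)
  r1 <- run_secretome_pipeline(mfi, conc)
  r2 <- run_secretome_pipeline(mfi, conc)
  expect_identical(r1$pca$scores, r2$pca$scores)
  expect_identical(r1$clusters$order, r2$clusters$order)
  expect_identical(r1$report$n_samples_mfi, 48L)
  expect_false(any(c("IL-1 beta", "TNF alpha") %in% r1$pca$analytes))
  # emulated removal of one compromised sample leaves 47
  drop <- which(mfi$sample_meta$condition == "baseline" &
                  mfi$sample_meta$compartment == "chondrocyte" &
                  mfi$sample_meta$day == 7)[1]
  mfi47 <- cytokine_table(mfi$values[-drop, ], mfi$sample_meta[-drop, ],
                          mode = "MFI")
  conc47 <- cytokine_table(conc$values[-drop, ], conc$sample_meta[-drop, ])
  r47 <- run_secretome_pipeline(mfi47, conc47)
  expect_identical(nrow(r47$pca$scores), 47L)
})

test_that("condition effects concentrate variance in the leading components", {
  null_tab <- generate_cytokine_table(
    effects = default_cytokine_effects()[0, ], spike_fold = 1,
    mode = "MFI", seed = 26)
  strong <- generate_cytokine_table(mode = "MFI", seed = 26)
  pc12 <- function(tab) {
    p <- pca_samples(zscore_analytes(impute_missing(tab)),
                     exclude_analytes = c("IL-1 beta", "TNF alpha"))
    sum(p$explained[1:2])
  }
  expect_gt(pc12(strong), pc12(null_tab))
})

test_that("cytokine tables round-trip through CSV", {
  tab <- generate_cytokine_table(seed = 27)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cytokine_csv(tab, f)
  back <- read_cytokine_csv(f)
  expect_equal(unclass(back$values), unclass(tab$values),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$sample_meta$condition, tab$sample_meta$condition)
})
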