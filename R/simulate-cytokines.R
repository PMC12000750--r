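#' Generate a structured synthetic cytokine table
#'
#' One row per cell of a fully crossed design (sex x condition x compartment
#' x day x replicate; the default 2 x 2 x 2 x 2 x 3 design gives 48
#' samples). Analyte values are log-normal around a per-analyte baseline
#' with multiplicative condition/compartment effects, spiked stimulation
#' analytes elevated in inflamed rows, and a configurable fraction of
#' entries missing completely at random.
#'
#' @param design list of factor levels: `sex`, `condition`, `compartment`,
#'   `day`, and a `replicates` count (>= 1).
#' @param analytes analyte panel (default the 20-plex inflammation panel).
#' @param effects data frame of multiplicative shifts: columns `analyte`,
#'   `factor`, `level`, `fold`. The default drives IL-6, IL-8 and MCP-1 up
#'   under inflammation (the dominant secreted mediators) with a milder
#'   compartment effect.
#' @param baseline_log_mean,log_sd location and spread of log baselines.
#' @param spike_analytes analytes spiked into the medium to induce
#'   inflammation; elevated strongly in inflamed rows.
#' @param spike_fold fold elevation of spiked analytes under inflammation.
#' @param missing_frac fraction of entries set missing at random.
#' @param response_sd per-sample log-scale spread of the inflammatory
#'   response magnitude (a latent donor/unit factor scaling all effect
#'   folds of an inflamed sample together, which makes responsive analytes
#'   co-vary as they do in perfused units).
#' @param mode `"MFI"` or `"concentration"`.
#' @param seed RNG seed.
#' @return a [cytokine_table()] with attribute `truth` (effects table and
#'   design).
#' @export
generate_cytokine_table <- function(design = list(
                                      sex = c("female", "male"),
                                      condition = c("baseline", "inflamed"),
                                      compartment = c("osteoblast",
                                                      "chondrocyte"),
                                      day = c(3, 7), replicates = 3),
                                    analytes = inflammation_panel_20plex(),
                                    effects = default_cytokine_effects(),
                                    baseline_log_mean = log(50),
                                    log_sd = 0.35,
                                    spike_analytes = c("IL-1 beta",
                                                       "TNF alpha"),
                                    spike_fold = 30,
                                    missing_frac = 0.05,
                                    response_sd = 0.2,
                                    mode = "concentration",
                                    seed = 1L) {
  if (is.null(design$replicates) || design$replicates < 1)
    oc_abort("design must include >= 1 replicate", "invalid_design")
  if (nrow(effects) > 0 && !all(effects$analyte %in% analytes))
    oc_abort("effects reference analytes outside the declared panel",
             "invalid_design")
  set.seed(seed)
  meta <- expand.grid(replicate = seq_len(design$replicates),
                      day = design$day, compartment = design$compartment,
                      condition = design$condition, sex = design$sex,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("sex", "condition", "compartment", "day", "replicate")]
  n <- nrow(meta)
  meta$sample_id <- sprintf("S%02d", seq_len(n))
  # per-analyte baselines spread over ~2 decades
  base <- exp(baseline_log_mean + seq(-1.5, 1.5,
                                      length.out = length(analytes)))
  names(base) <- analytes
  logv <- matrix(rnorm(n * length(analytes), 0, log_sd), n,
                 dimnames = list(meta$sample_id, analytes))
  logv <- sweep(logv, 2, log(base), `+`)
  eff_log <- matrix(0, n, length(analytes),
                    dimnames = list(meta$sample_id, analytes))
  apply_fold <- function(analyte, fac, lev, fold) {
    rows <- meta[[fac]] == lev
    eff_log[rows, analyte] <<- eff_log[rows, analyte] + log(fold)
  }
  if (nrow(effects) > 0)
    for (k in seq_len(nrow(effects)))
      apply_fold(effects$analyte[k], effects$factor[k], effects$level[k],
                 effects$fold[k])
  for (a in intersect(spike_analytes, analytes))
    apply_fold(a, "condition", "inflamed", spike_fold)
  latent <- rep(1, n)
  if (response_sd > 0) {
    inflamed <- meta$condition == "inflamed"
    latent[inflamed] <- exp(rnorm(sum(inflamed), 0, response_sd))
  }
  values <- exp(logv + eff_log * latent)
  if (missing_frac > 0)
    values[runif(length(values)) < missing_frac] <- NA_real_
  tab <- cytokine_table(values, meta, mode = mode)
  attr(tab, "truth") <- list(effects = effects, design = design,
                             spike_analytes = spike_analytes,
                             spike_fold = spike_fold)
  tab
}

#' @rdname generate_cytokine_table
#' @export
default_cytokine_effects <- function() {
  # inflammatory stimulation upregulates a broad mediator panel, with IL-6,
  # IL-8 and MCP-1 (CCL2) as the dominant secreted drivers and the related
  # chemokines co-regulated; osteoblast and chondrocyte outlets differ
  # moderately for the major interleukins
  data.frame(
    analyte = c("IL-6", "IL-8", "MCP-1", "MIP-1 alpha", "MIP-1 beta",
                "IP-10", "GM-CSF", "IFN gamma", "IL-1 alpha", "ICAM-1",
                "IL-6", "IL-8"),
    factor = c(rep("condition", 10), "compartment", "compartment"),
    level = c(rep("inflamed", 10), "osteoblast", "osteoblast"),
    fold = c(10, 8, 6, 3, 3, 3, 2, 2, 2, 1.5, 1.5, 1.5),
    stringsAsFactors = FALSE)
}

#' Generate a cytokine table with block correlation structure
#'
#' Latent-factor construction: analytes within a block share a common factor
#' (pairwise correlation ~ `rho`), between-block correlation ~ 0. Used to
#' validate that correlation-distance clustering recovers co-varying analyte
#' sets.
#'
#' @param n_samples rows.
#' @param block_sizes analytes per block.
#' @param rho within-block correlation.
#' @param seed RNG seed.
#' @return a [cytokine_table()] with attribute `blocks` (integer block id
#'   per analyte).
#' @export
generate_block_cytokine_table <- function(n_samples = 48,
                                          block_sizes = c(5, 5), rho = 0.9,
                                          seed = 1L) {
  set.seed(seed)
  n_an <- sum(block_sizes)
  blocks <- rep(seq_along(block_sizes), block_sizes)
  f <- matrix(rnorm(n_samples * length(block_sizes)), n_samples)
  v <- sapply(seq_len(n_an), function(j)
    sqrt(rho) * f[, blocks[j]] + sqrt(1 - rho) * rnorm(n_samples))
  colnames(v) <- sprintf("A%02d", seq_len(n_an))
  meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)))
  tab <- cytokine_table(v - min(v) + 1, meta, mode = "concentration")
  attr(tab, "blocks") <- setNames(blocks, colnames(v))
  tab
}

#' Read / write cytokine tables as CSV with a metadata column block
#'
#' Metadata columns (`sample_id`, `sex`, `condition`, `compartment`, `day`,
#' `replicate`; whichever are present) precede the analyte columns.
#'
#' @param table a [cytokine_table()].
#' @param path CSV file.
#' @param mode assay mode on read.
#' @return `write_cytokine_csv` returns `path` invisibly;
#'   `read_cytokine_csv` returns a [cytokine_table()].
#' @export
write_cytokine_csv <- function(table, path) {
  write.csv(cbind(table$sample_meta, as.data.frame(table$values)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cytokine_csv
#' @export
read_cytokine_csv <- function(path, mode = "concentration") {
  if (!file.exists(path))
    oc_abort(sprintf("file not found: %s", path), "missing_file")
  tab <- read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("sample_id", "sex", "condition", "compartment",
                           "day", "replicate"), names(tab))
  cytokine_table(as.matrix(tab[, setdiff(names(tab), meta_cols),
                               drop = FALSE]),
                 tab[, meta_cols, drop = FALSE], mode = mode)
}
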