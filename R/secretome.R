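#' Samples-by-analytes cytokine table
#'
#' Container for multiplex immunoassay measurements: a numeric matrix
#' (samples in rows, analytes in columns, possibly with missing entries)
#' aligned 1:1 with per-sample metadata.
#'
#' @param values numeric matrix, samples x analytes; column names are the
#'   analyte names (unique).
#' @param sample_meta data frame with one row per sample (typically columns
#'   `sample_id`, `sex`, `condition`, `compartment`, `day`).
#' @param mode `"MFI"` (raw median fluorescence intensity) or
#'   `"concentration"` (standard-curve converted).
#' @return object of class `cytokine_table`.
#' @export
cytokine_table <- function(values, sample_meta, mode = "concentration") {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    oc_abort("analyte (column) names must be present and unique",
             "invalid_input")
  if (nrow(values) != nrow(sample_meta))
    oc_abort("sample metadata rows must align 1:1 with value rows",
             "invalid_input")
  if (!mode %in% c("MFI", "concentration"))
    oc_abort("`mode` must be \"MFI\" or \"concentration\"", "invalid_input")
  structure(list(values = values, sample_meta = sample_meta, mode = mode),
            class = "cytokine_table")
}

#' @export
print.cytokine_table <- function(x, ...) {
  cat(sprintf("<cytokine_table> %d samples x %d analytes (%s), %d missing\n",
              nrow(x$values), ncol(x$values), x$mode, sum(is.na(x$values))))
  invisible(x)
}

#' The 20-analyte inflammation multiplex panel
#' @return character vector of analyte names.
#' @export
inflammation_panel_20plex <- function() {
  c("GM-CSF", "IFN alpha", "IFN gamma", "IL-1 alpha", "IL-1 beta", "IL-4",
    "IL-6", "IL-8", "IL-10", "IL-12p70", "IL-13", "IL-17A", "TNF alpha",
    "IP-10", "MCP-1", "MIP-1 alpha", "MIP-1 beta", "ICAM-1", "sCD62E",
    "sCD62P")
}

#' Impute missing values by the 10%-of-minimum rule
#'
#' Every missing entry is replaced with 10% of the minimum non-missing value
#' of the corresponding analyte; non-missing entries are untouched.
#'
#' @param table a [cytokine_table()]; every analyte with missing entries must
#'   have at least one observed value.
#' @return the imputed [cytokine_table()].
#' @export
impute_missing <- function(table) {
  v <- table$values
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    if (all(miss))
      oc_abort(sprintf("analyte '%s' has no observed values: cannot impute",
                       colnames(v)[j]), "unimputable_analyte")
    v[miss, j] <- 0.1 * min(v[!miss, j])
  }
  table$values <- v
  table
}

#' Remove low-variance analytes
#'
#' Drops analytes whose sample variance (unbiased, n-1 denominator) is
#' strictly below the threshold; "below 0.9" is strict, so a variance of
#' exactly 0.9 is retained.
#'
#' @param table an imputed [cytokine_table()].
#' @param threshold variance cutoff (default 0.9).
#' @return list: `table` (filtered), `removed` (analyte names).
#' @export
filter_low_variance <- function(table, threshold = 0.9) {
  vars <- apply(table$values, 2, var)
  removed <- colnames(table$values)[vars < threshold]
  if (length(removed) == ncol(table$values))
    oc_abort("all analytes fall below the variance threshold", "empty_table")
  table$values <- table$values[, !(colnames(table$values) %in% removed),
                               drop = FALSE]
  list(table = table, removed = removed)
}

#' Z-score standardization per analyte
#'
#' Scales each analyte to zero mean and unit variance.
#'
#' @param table a [cytokine_table()] with no zero-variance analytes.
#' @return the standardized [cytokine_table()].
#' @export
zscore_analytes <- function(table) {
  sds <- apply(table$values, 2, sd)
  if (any(sds == 0))
    oc_abort(sprintf("zero-variance analyte(s): %s",
                     paste(colnames(table$values)[sds == 0], collapse = ", ")),
             "zero_variance")
  table$values <- scale(table$values)
  attr(table$values, "scaled:center") <- NULL
  attr(table$values, "scaled:scale") <- NULL
  table
}

#' Principal component analysis of samples in analyte space
#'
#' PCA of the (standardized) samples-by-analytes matrix. The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' which removes the decomposition's sign indeterminacy. Explained-variance
#' fractions equal the covariance eigenvalues divided by their sum.
#'
#' @param table a standardized [cytokine_table()].
#' @param exclude_analytes analytes dropped before the decomposition (e.g.
#'   spiked stimuli whose levels would bias sample clustering).
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (analytes x components), `explained` (fractions,
#'   non-increasing).
#' @export
pca_samples <- function(table, exclude_analytes = NULL) {
  v <- table$values
  if (!is.null(exclude_analytes))
    v <- v[, !(colnames(v) %in% exclude_analytes), drop = FALSE]
  if (ncol(v) < 2)
    oc_abort("fewer than 2 analytes after exclusion", "undersized_input")
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 analytes = colnames(v)),
            class = "pca_result")
}

#' Analytes contributing most to selected principal components
#'
#' The contribution of analyte j is its squared loading on each requested
#' component weighted by that component's explained-variance fraction,
#' summed over the components and normalized so all contributions sum to 1.
#' Ties rank alphabetically.
#'
#' @param result a [pca_samples()] result.
#' @param components component indices (default PC1 and PC2).
#' @param n how many top analytes to return; if larger than the panel, all
#'   are returned with a message.
#' @return data frame ranked by descending contribution: `analyte`,
#'   `contribution`.
#' @export
top_contributors <- function(result, components = c(1, 2), n = 5) {
  if (any(components > ncol(result$loadings)))
    oc_abort("requested component does not exist", "invalid_input")
  w <- result$explained[components]
  contrib <- as.numeric(result$loadings[, components, drop = FALSE]^2 %*% w)
  contrib <- contrib / sum(contrib)
  names(contrib) <- result$analytes
  ord <- order(-contrib, names(contrib))
  if (n > length(contrib)) {
    message(sprintf("only %d analytes available; returning all",
                    length(contrib)))
    n <- length(contrib)
  }
  data.frame(analyte = names(contrib)[ord][seq_len(n)],
             contribution = as.numeric(contrib[ord])[seq_len(n)],
             row.names = NULL)
}

#' Hierarchical clustering of analytes by correlation distance
#'
#' Pairwise distance `d(j, k) = 1 - Pearson correlation` between analyte
#' columns, agglomerated by complete linkage (whose merge heights are
#' monotone non-decreasing). The result backs a clustered correlation
#' heatmap.
#'
#' @param table a standardized [cytokine_table()] with >= 2 analytes.
#' @return object of class `cluster_result`: `correlation` (symmetric, unit
#'   diagonal), `tree` (an [stats::hclust] merge tree), `order` (leaf order).
#' @export
cluster_analytes <- function(table) {
  v <- table$values
  if (ncol(v) < 2) oc_abort("need >= 2 analytes", "undersized_input")
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    oc_abort("zero-variance analyte: correlation undefined",
             "undefined_correlation")
  cm <- cor(v)
  tree <- hclust(as.dist(1 - cm), method = "complete")
  structure(list(correlation = cm, tree = tree,
                 order = colnames(v)[tree$order]),
            class = "cluster_result")
}

#' Export a cluster tree as Newick text
#' @param clusters a [cluster_analytes()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(clusters, path) {
  ape::write.tree(ape::as.phylo(clusters$tree), file = path)
  invisible(path)
}

#' Run the full secretome pipeline on the paired MFI / concentration tables
#'
#' Mirrors the two-dataset design of the assay analysis. The MFI table
#' answers "which samples cluster together": imputation, spiked-analyte
#' exclusion, z-scoring, then sample-space PCA (no variance filter on this
#' path). The concentration table answers "which analytes co-vary":
#' imputation, low-variance filtering, z-scoring, then correlation-distance
#' complete-linkage clustering. The order impute -> filter -> z-score ->
#' decompose/cluster is fixed by this single entry point.
#'
#' @param mfi_table,conc_table [cytokine_table()]s sharing one analyte panel.
#' @param config an [analysis_config()] (`excluded_analytes`,
#'   `variance_threshold`).
#' @return list: `pca` (a `pca_result`), `clusters` (a `cluster_result`),
#'   `contributions` (top PC1-2 contributors), `report` (dropped analytes and
#'   parameters).
#' @export
run_secretome_pipeline <- function(mfi_table, conc_table,
                                   config = analysis_config()) {
  if (!setequal(colnames(mfi_table$values), colnames(conc_table$values)))
    oc_abort("MFI and concentration tables must share the analyte panel",
             "invalid_input")
  mfi <- zscore_analytes(impute_missing(mfi_table))
  pca <- pca_samples(mfi, exclude_analytes = config$excluded_analytes)
  contrib <- top_contributors(pca, components = c(1, 2),
                              n = length(pca$analytes))
  conc <- impute_missing(conc_table)
  flt <- filter_low_variance(conc, config$variance_threshold)
  clusters <- cluster_analytes(zscore_analytes(flt$table))
  list(pca = pca, clusters = clusters, contributions = contrib,
       report = list(n_samples_mfi = nrow(mfi_table$values),
                     n_samples_concentration = nrow(conc_table$values),
                     excluded_from_pca = config$excluded_analytes,
                     removed_low_variance = flt$removed,
                     variance_threshold = config$variance_threshold,
                     note = paste("MFI path: imputation + z-score only",
                                  "(no variance filter before PCA)")))
}
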