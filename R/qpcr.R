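#' Relative gene expression from qPCR quantification cycles
#'
#' Computes relative mRNA expression against a housekeeping gene as
#' `2^(Ct_reference - Ct_target)` (18S ribosomal RNA is the usual reference
#' in this workflow). Vectorized over measurements.
#'
#' @param ct_reference quantification cycle(s) of the housekeeping gene;
#'   finite and positive.
#' @param ct_target quantification cycle(s) of the target gene.
#' @return fold change(s), strictly positive. A target amplifying later than
#'   the reference (higher Ct) gives a value below 1.
#' @examples
#' relative_expression(15, 15)   # 1
#' relative_expression(20, 10)   # 1024
#' @export
relative_expression <- function(ct_reference, ct_target) {
  if (!is.numeric(ct_reference) || !is.numeric(ct_target) ||
      any(!is.finite(ct_reference)) || any(!is.finite(ct_target)) ||
      any(ct_reference <= 0) || any(ct_target <= 0))
    oc_abort("Ct values must be finite and > 0", "invalid_input")
  if (length(ct_reference) != length(ct_target))
    oc_abort("Ct vectors must have equal length", "invalid_input")
  2^(ct_reference - ct_target)
}

#' Fold-change table from a Ct table
#'
#' Applies [relative_expression()] row-wise to a table with columns
#' `gene`, `ct_reference` and `ct_target` (extra columns are carried through).
#'
#' @param ct_table data frame of Ct measurements.
#' @return the same table with a `fold_change` column appended.
#' @export
qpcr_fold_changes <- function(ct_table) {
  need <- c("gene", "ct_reference", "ct_target")
  if (!all(need %in% names(ct_table)))
    oc_abort(paste("Ct table must have columns:", paste(need, collapse = ", ")),
             "invalid_input")
  ct_table$fold_change <- relative_expression(ct_table$ct_reference,
                                              ct_table$ct_target)
  ct_table
}
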