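# Differential-expression table thresholding: Benjamini-Hochberg
# adjustment and the published log-fold-change / adjusted-p filter.
# The DE test itself (negative-binomial modelling) is an external stage;
# only the published thresholding rules live here.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]): sort
#' ascending, `adj_i = min_{j >= i} m * p_j / j`, capped at 1; input
#' order is preserved in the output.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Threshold a differential-expression table
#'
#' Splits records into overexpressed (`adjusted_p < alpha` and
#' `log2 fold change >= lfc`) and underexpressed (`adjusted_p < alpha`
#' and `log2 fold change <= -lfc`); the p cutoff is strict and the
#' fold-change cutoffs are inclusive, matching the printed symbols
#' (p < 0.01, LFC >= 2 / <= -2).
#'
#' @param records Data.frame with columns `gene_id`, `lfc` and
#'   `adjusted_p` (or `p_value` plus a missing `adjusted_p`, in which
#'   case [bh_adjust()] is applied first).
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param lfc Absolute log2-fold-change cutoff (default 2).
#' @return List with character vectors `overexpressed` and
#'   `underexpressed` of gene ids.
#' @export
filter_de_table <- function(records, alpha = 0.01, lfc = 2) {
  stopifnot(all(c("gene_id", "lfc") %in% names(records)))
  if (!"adjusted_p" %in% names(records)) {
    if (!"p_value" %in% names(records))
      stop("records need adjusted_p or p_value")
    records$adjusted_p <- bh_adjust(records$p_value)
  }
  if (any(records$adjusted_p < 0 | records$adjusted_p > 1))
    stop("adjusted p-values must lie in [0, 1]")
  sig <- records$adjusted_p < alpha
  list(
    overexpressed = records$gene_id[sig & records$lfc >= lfc],
    underexpressed = records$gene_id[sig & records$lfc <= -lfc])
}
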