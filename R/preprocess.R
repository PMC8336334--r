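#' Gene-wise z-score normalization
#'
#' Centers and scales each gene row to mean 0 and population (n-denominator)
#' standard deviation 1. Constant genes cannot be scaled and are dropped; the
#' drop count is reported via message and the `n_dropped` attribute.
#'
#' @param m Numeric gene-by-sample matrix (>= 2 samples).
#' @return Matrix of the same shape minus dropped rows, with
#'   `value_scale = "zscore"`.
#' @export
zscore_by_gene <- function(m) {
  if (ncol(m) < 2L) stop("z-score normalization needs >= 2 samples")
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2)) # population SD
  const <- sdp == 0
  if (all(const)) stop("all genes are constant; nothing to normalize")
  if (any(const))
    message("dropped ", sum(const), " constant gene(s) at z-score stage")
  out <- (m[!const, , drop = FALSE] - mu[!const]) / sdp[!const]
  attr(out, "value_scale") <- "zscore"
  attr(out, "n_dropped") <- sum(const)
  out
}

#' Gene-wise min-max normalization
#'
#' Rescales each gene row linearly onto [0, 1], producing a non-negative
#' matrix suitable as NMF input. Run after [zscore_by_gene()], which removes
#' constant genes.
#'
#' @param m Numeric gene-by-sample matrix with no constant rows.
#' @return Matrix of the same shape with every row spanning exactly [0, 1]
#'   and `value_scale = "minmax"`.
#' @export
minmax_by_gene <- function(m) {
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  const <- hi == lo
  if (any(const))
    stop("constant gene row(s) cannot be min-max scaled: ",
         paste(utils::head(rownames(m)[const], 5L), collapse = ", "))
  out <- (m - lo) / (hi - lo)
  attr(out, "value_scale") <- "minmax"
  out
}

#' Normalize expression for the training pipeline
#'
#' Applies the pipeline's fixed normalization order: gene-wise z-score then
#' gene-wise min-max. The result is non-negative and rank-preserving within
#' each gene row.
#'
#' @param m Numeric gene-by-sample matrix on the raw scale.
#' @return Matrix with each row spanning [0, 1] (`value_scale = "minmax"`).
#' @export
normalize_expression <- function(m) {
  minmax_by_gene(zscore_by_gene(m))
}

#' Align an expression matrix with a clinical table
#'
#' Restricts both inputs to the intersection of their sample identifiers, in
#' the expression matrix's column order.
#'
#' @param m Numeric gene-by-sample matrix.
#' @param clinical Clinical `data.frame` with a `sample_id` column.
#' @return List with elements `expression`, `clinical` and `n_common`.
#' @export
align_to_clinical <- function(m, clinical) {
  common <- intersect(colnames(m), clinical$sample_id)
  if (length(common) == 0L)
    stop("no samples shared between expression matrix and clinical table")
  common <- colnames(m)[colnames(m) %in% common]
  me <- m[, common, drop = FALSE]
  attr(me, "value_scale") <- attr(m, "value_scale")
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  message(length(common), " samples shared between expression and clinical data")
  list(expression = me, clinical = cl, n_common = length(common))
}
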